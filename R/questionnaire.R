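# Food-frequency questionnaire scoring.

exposure_points <- c(yes = 10, unsure = 1, no = 0)
freq_points <- c(le2 = 1, "3to5" = 3, ge6 = 5)
dur_points <- c(lt6m = 1, "6to12m" = 2, "1to2y" = 3, gt2y = 4)

#' Score a food-frequency questionnaire response
#'
#' Each of the five category questions is scored as the product of the
#' exposure points (yes 10, unsure 1, no 0), the weekly-frequency points
#' (<=2 times 1, 3-5 times 3, >=6 times 5) and the duration points
#' (< 0.5 y 1, 0.5-1 y 2, 1-2 y 3, > 2 y 4), giving at most 200 points per
#' category and 1000 in total.
#'
#' @param resp data frame with one row per category and columns `category`,
#'   `exposed` (`yes`/`unsure`/`no`), `freq_cat` (`le2`/`3to5`/`ge6`),
#'   `dur_cat` (`lt6m`/`6to12m`/`1to2y`/`gt2y`). Frequency and duration may
#'   be `NA` when `exposed == "no"` (the category then scores 0).
#' @return A list with `total` (0-1000) and `per_category` (named, 0-200).
#' @export
#' @examples
#' resp <- data.frame(category = food_categories(), exposed = "yes",
#'                    freq_cat = "ge6", dur_cat = "gt2y")
#' score_questionnaire(resp)$total  # 1000
score_questionnaire <- function(resp) {
  stopifnot(all(c("category", "exposed", "freq_cat", "dur_cat") %in%
                  names(resp)))
  if (!all(resp$exposed %in% names(exposure_points))) {
    stop("exposed must be one of yes/unsure/no", call. = FALSE)
  }
  sc <- numeric(nrow(resp))
  for (i in seq_len(nrow(resp))) {
    if (resp$exposed[i] == "no") next
    f <- resp$freq_cat[i]; d <- resp$dur_cat[i]
    if (is.na(f) || is.na(d) || !f %in% names(freq_points) ||
        !d %in% names(dur_points)) {
      stop("frequency and duration categories required when exposed != no",
           call. = FALSE)
    }
    sc[i] <- exposure_points[[resp$exposed[i]]] * freq_points[[f]] *
      dur_points[[d]]
  }
  names(sc) <- resp$category
  list(total = sum(sc), per_category = sc)
}
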
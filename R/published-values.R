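# Reference values published by the agencies / incident risk assessment.
# These small tables are inputs and test anchors, not computed results.

#' Published agency survey counts for the 2011 DEHP incident
#'
#' Numbers of food-product records examined before 2011-05-31 by the
#' Kaohsiung Bureau of Health (KBOH) and the Taiwan FDA (TFDA), and how many
#' of them were detected with DEHP at or above the 1 ppm screening level,
#' for each of the five contaminated food categories.
#'
#' @return A data frame with columns `category`, `agency`, `detected`,
#'   `total`.
#' @seealso [published_category_estimates()], [published_exposure_counts()]
#' @export
#' @examples
#' x <- published_survey_counts()
#' with(x[x$agency == "KBOH", ], sum(total))  # 1927 KBOH records
published_survey_counts <- function() {
  data.frame(
    category = rep(food_categories(), each = 2),
    agency   = rep(c("KBOH", "TFDA"), times = 5),
    detected = c(0L, 4L, 2L, 1L, 1L, 9L, 1L, 9L, 110L, 16L),
    total    = c(7L, 22L, 46L, 29L, 73L, 109L, 25L, 58L, 1166L, 47L),
    stringsAsFactors = FALSE
  )
}

#' Published concentration-model estimates by food category
#'
#' Posterior summaries of the concentration model reported by the incident
#' risk assessment: detection probability `p_d` (DEHP >= 1 ppm), the
#' TFDA/KBOH non-detection odds ratio `or_nd` (= exp(beta)), the expected
#' tainted-food concentration `e_y` (ppm), the sub-threshold and zero masses
#' `p_1` and `p_0`, and the expected overall-category concentration `e_c`
#' (ppm). Used as reference inputs for deterministic composition checks and
#' for point-mass posterior construction.
#'
#' @return A data frame, one row per food category.
#' @export
#' @examples
#' est <- published_category_estimates()
#' tea <- est[est$category == "tea_drinks", ]
#' ec_composition(tea$p_d, tea$e_y, tea$p_1)  # ~0.8 ppm
published_category_estimates <- function() {
  data.frame(
    category = food_categories(),
    p_d   = c(0.058, 0.042, 0.014, 0.041, 0.105),
    or_nd = c(44.1, 0.8, 6.3, 5.6, 4.9),
    e_y   = c(12.9, 19.1, 35.3, 123.1, 62.1),
    p_1   = c(0.014, 0.013, 0.038, 0.019, 0.018),
    p_0   = c(0.941, 0.958, 0.985, 0.959, 0.893),
    e_c   = c(0.8, 0.8, 0.5, 5.1, 6.6),
    stringsAsFactors = FALSE
  )
}

#' Published exposure-group classification counts
#'
#' Counts of eligible participants per age group falling in the low
#' (< 20), medium (20-50), high (50-100) and very high (> 100
#' ug/kg_bw/day) AvDI exposure groups, with and without the window-period
#' adjustment, as reported by the incident risk assessment.
#'
#' @return A data frame with columns `window`, `age_group`, `low`, `medium`,
#'   `high`, `very_high`, `total`.
#' @export
published_exposure_counts <- function() {
  data.frame(
    window = rep(c("without", "with"), each = 3),
    age_group = rep(c("children", "adolescents", "adults"), times = 2),
    low       = c(85L, 9L, 82L, 143L, 11L, 89L),
    medium    = c(83L, 2L, 9L, 63L, 1L, 6L),
    high      = c(34L, 1L, 3L, 15L, 0L, 0L),
    very_high = c(25L, 0L, 1L, 6L, 0L, 0L),
    total     = c(227L, 12L, 95L, 227L, 12L, 95L),
    stringsAsFactors = FALSE
  )
}
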
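#' Exposure-group scheme
#'
#' Thresholds (ug/kg_bw/day) partitioning estimated AvDIs into low, medium,
#' high and very-high exposure groups. The defaults follow the US EPA
#' reference dose (20), the EU tolerable daily intake (50) and 100.
#'
#' @param thresholds strictly increasing positive thresholds.
#' @return Object of class `exposure_scheme`.
#' @export
exposure_scheme <- function(thresholds = c(20, 50, 100)) {
  if (any(diff(thresholds) <= 0) || any(thresholds <= 0)) {
    stop("thresholds must be strictly increasing and positive",
         call. = FALSE)
  }
  structure(list(thresholds = thresholds,
                 labels = c("low", "medium", "high", "very_high")),
            class = "exposure_scheme")
}

#' Classify AvDI values into exposure groups
#'
#' Left-closed assignment on the thresholds: a value of exactly 20 is
#' `medium` ("< 20" is low, "20-50" medium, "50-100" high, "> 100" very
#' high).
#'
#' @param avdi numeric AvDI values (ug/kg_bw/day, >= 0).
#' @param scheme an [exposure_scheme()].
#' @return Factor of group labels with levels low/medium/high/very_high.
#' @export
#' @examples
#' classify_exposure(c(0, 19.999, 20, 414.1))
classify_exposure <- function(avdi, scheme = exposure_scheme()) {
  if (any(!is.finite(avdi)) || any(avdi < 0)) {
    stop("AvDI values must be non-negative", call. = FALSE)
  }
  idx <- findInterval(avdi, scheme$thresholds) + 1L
  factor(scheme$labels[idx], levels = scheme$labels)
}

#' Exposure-group table by age group
#'
#' Counts and integer percentages of classified participants per age group,
#' one row per age group.
#'
#' @param classified data frame with columns `age_group` and `group`
#'   (a factor from [classify_exposure()]).
#' @return Data frame with count and percentage columns per exposure group
#'   plus the row total `n`.
#' @export
#' @examples
#' df <- data.frame(age_group = "children",
#'                  group = classify_exposure(c(5, 25, 60, 150)))
#' exposure_table(df)
exposure_table <- function(classified) {
  tab <- table(classified$age_group, classified$group)
  out <- data.frame(age_group = rownames(tab), stringsAsFactors = FALSE)
  n <- rowSums(tab)
  for (g in colnames(tab)) {
    out[[g]] <- as.integer(tab[, g])
    out[[paste0(g, "_pct")]] <- ifelse(n > 0,
                                       as.integer(round(100 * tab[, g] / n)),
                                       0L)
  }
  out$n <- as.integer(n)
  rownames(out) <- NULL
  out
}

#' Chi-square comparison of exposure-group distributions
#'
#' Pearson chi-square test (no continuity correction) on a groups x
#' exposure-classes count table; all-zero columns are dropped first.
#'
#' @param counts matrix of non-negative integer counts (e.g. 2 x 4:
#'   children vs adults by exposure group).
#' @return List with `statistic`, `df` and `p_value`.
#' @export
#' @examples
#' m <- rbind(children = c(85, 83, 34, 25), adults = c(82, 9, 3, 1))
#' compare_groups_chisq(m)$p_value  # << 0.0001
compare_groups_chisq <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  counts <- counts[, colSums(counts) > 0, drop = FALSE]
  counts <- counts[rowSums(counts) > 0, , drop = FALSE]
  if (sum(counts) == 0 || nrow(counts) < 2 || ncol(counts) < 2) {
    stop("need at least a 2x2 table with positive counts", call. = FALSE)
  }
  ht <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value))
}

#' Correlations between intake components
#'
#' Correlation (default Pearson) of the background component `AvDI_ENV`
#' with the dietary components `AvDI_QN` and `AvDI_SF`, per age stratum,
#' with two-sided p-values. Strata with fewer than 3 participants or a
#' constant component yield `NA` coefficients.
#'
#' @param estimates data frame with columns `age_group`, `avdi_env`,
#'   `avdi_qn`, `avdi_sf` (per-participant posterior means).
#' @param method correlation type (`"pearson"` or `"spearman"`).
#' @return Data frame with one row per age group x component pair.
#' @export
component_correlations <- function(estimates, method = "pearson") {
  pairs <- c("avdi_qn", "avdi_sf")
  rows <- list()
  for (g in unique(estimates$age_group)) {
    sub <- estimates[estimates$age_group == g, ]
    for (p in pairs) {
      est <- NA_real_; pval <- NA_real_
      if (nrow(sub) >= 3 && stats::sd(sub$avdi_env) > 0 &&
          stats::sd(sub[[p]]) > 0) {
        ct <- suppressWarnings(
          stats::cor.test(sub$avdi_env, sub[[p]], method = method,
                          exact = FALSE))
        est <- unname(ct$estimate); pval <- ct$p.value
      }
      rows[[length(rows) + 1L]] <- data.frame(
        age_group = g, component = p, cor = est, p_value = pval, n = nrow(sub),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Summarise posterior intake draws
#'
#' Mean, median and central 95% interval (type-7 linear-interpolation
#' quantiles) of each intake component of an [reconstruct_participant()]
#' result, or of any data frame of draws.
#'
#' @param draws an `avdi_draws` object or a data frame of draws.
#' @return Data frame with one row per component.
#' @export
summarize_posterior <- function(draws) {
  d <- if (inherits(draws, "avdi_draws")) draws$draws else as.data.frame(draws)
  if (is.null(d) || nrow(d) == 0) stop("empty draws", call. = FALSE)
  comp <- names(d)
  data.frame(
    component = comp,
    mean = vapply(d, mean, numeric(1)),
    median = vapply(d, stats::median, numeric(1)),
    q2.5 = vapply(d, stats::quantile, numeric(1), probs = 0.025),
    q97.5 = vapply(d, stats::quantile, numeric(1), probs = 0.975),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
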
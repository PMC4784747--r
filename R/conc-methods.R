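# S3 methods for fitted concentration models.

#' @export
print.conc_fit <- function(x, ...) {
  cat("Bayesian DEHP concentration model\n")
  cat(sprintf("  categories: %s\n",
              paste(names(x$categories), collapse = ", ")))
  cat(sprintf("  bins: [%s] ppm (cap %g); draws per category: %d\n",
              paste(x$bins$lower, collapse = ", "), x$bins$upper[x$bins$n_bins],
              nrow(x$categories[[1]]$draws)))
  flagged <- names(Filter(function(p) any(p$rhat > 1.1, na.rm = TRUE),
                          x$categories))
  if (length(flagged)) {
    cat(sprintf("  convergence flags (R-hat > 1.1): %s\n",
                paste(flagged, collapse = ", ")))
  }
  invisible(x)
}

#' Posterior summary table of a concentration fit
#'
#' One row per category with posterior means and 95% intervals of the
#' detection probability `p_D`, the non-detection odds ratio `exp(beta)`,
#' the expected tainted-food concentration `E(Y)`, the sub-threshold and
#' zero masses `p_1`/`p_0`, and the expected overall concentration `E(C)`.
#'
#' @param object a `conc_fit`.
#' @param ... unused.
#' @return A data frame of class `summary.conc_fit`.
#' @export
summary.conc_fit <- function(object, ...) {
  rows <- lapply(names(object$categories), function(cat) {
    d <- object$categories[[cat]]$draws
    q <- function(x, p) unname(stats::quantile(x, p))
    data.frame(
      category = cat,
      p_d = mean(d$p_d), p_d_lo = q(d$p_d, .025), p_d_hi = q(d$p_d, .975),
      or_nd = exp(stats::median(d$beta)),  # median: exp(beta) is heavy-tailed
      or_nd_lo = q(exp(d$beta), .025), or_nd_hi = q(exp(d$beta), .975),
      e_y = mean(d$e_y), e_y_lo = q(d$e_y, .025), e_y_hi = q(d$e_y, .975),
      p_1 = mean(d$p_1), p_0 = mean(d$p_0),
      e_c = mean(d$e_c), e_c_lo = q(d$e_c, .025), e_c_hi = q(d$e_c, .975),
      max_rhat = suppressWarnings(max(object$categories[[cat]]$rhat,
                                      na.rm = TRUE)),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("summary.conc_fit", "data.frame")
  out
}

#' @export
print.summary.conc_fit <- function(x, digits = 3, ...) {
  cat("Posterior summaries by food category\n")
  show <- data.frame(
    category = x$category,
    p_D = sprintf("%.3f (%.3f-%.3f)", x$p_d, x$p_d_lo, x$p_d_hi),
    `exp(beta)` = sprintf("%.1f (%.1f-%.1f)", x$or_nd, x$or_nd_lo,
                          x$or_nd_hi),
    `E(Y)` = sprintf("%.1f (%.1f-%.1f)", x$e_y, x$e_y_lo, x$e_y_hi),
    p_1 = sprintf("%.3f", x$p_1),
    p_0 = sprintf("%.3f", x$p_0),
    `E(C)` = sprintf("%.1f (%.1f-%.1f)", x$e_c, x$e_c_lo, x$e_c_hi),
    check.names = FALSE
  )
  print(show, row.names = FALSE)
  invisible(x)
}

#' Posterior-mean coefficients of a concentration fit
#'
#' @param object a `conc_fit`.
#' @param ... unused.
#' @return Matrix of posterior means (categories x parameters).
#' @export
coef.conc_fit <- function(object, ...) {
  s <- summary(object)
  m <- as.matrix(s[, c("p_d", "or_nd", "e_y", "p_1", "p_0", "e_c")])
  rownames(m) <- s$category
  m
}

#' Plot posterior expected concentrations
#'
#' Histograms of the posterior draws of the overall expected concentration
#' E(C) per category, on a log10 scale.
#'
#' @param x a `conc_fit`.
#' @param ... passed to [graphics::hist()].
#' @export
plot.conc_fit <- function(x, ...) {
  cats <- names(x$categories)
  op <- graphics::par(mfrow = c(ceiling(length(cats) / 2), 2),
                      mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (cat in cats) {
    ec <- x$categories[[cat]]$draws$e_c
    graphics::hist(log10(pmax(ec, 1e-4)), breaks = 40, main = cat,
                   xlab = "log10 E(C) [ppm]", col = "grey80", border = NA,
                   ...)
  }
  invisible(x)
}

#' Simulate exposure concentrations from a fitted model
#'
#' Convenience wrapper around [sample_concentration()].
#'
#' @param object a `conc_fit`.
#' @param nsim number of draws.
#' @param seed optional RNG seed.
#' @param category fitted category to sample from.
#' @param belief exposure belief (`"yes"`, `"unsure"`, `"no"`).
#' @param ... unused.
#' @return Numeric vector of concentration draws (ppm).
#' @export
simulate.conc_fit <- function(object, nsim = 1, seed = NULL,
                              category = NULL, belief = "unsure", ...) {
  sample_concentration(object, belief = belief, n = nsim, seed = seed,
                       category = category)
}

#' @export
print.category_posterior <- function(x, ...) {
  cat(sprintf("Category posterior: %s (%d draws, %d bins)\n", x$category,
              nrow(x$draws), x$bins$n_bins))
  ec <- expected_concentrations(x)
  cat(sprintf("  p_D = %.3f; E(Y) = %.1f ppm; E(C) = %.2f ppm\n",
              mean(x$draws$p_d), ec$e_y[["mean"]], ec$e_c[["mean"]]))
  invisible(x)
}
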
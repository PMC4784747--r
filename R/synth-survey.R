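#' Generate a synthetic DEHP concentration survey
#'
#' Simulates agency surveillance records of DEHP concentrations in the five
#' food categories. For each category and agency, a product is detected
#' (concentration >= 1 ppm) with a probability given by the baseline
#' (KBOH) detection probability and the agency non-detection odds ratio
#' `exp(true_beta)`. Detected concentrations are drawn from the category's
#' binned lognormal mixture (truncated to each bin); a configured fraction
#' of detected records carry no numeric value, mimicking the "> 1 ppm only"
#' quick-screening reports. A fraction of detected juice records are
#' concentrates whose measured value is `juice_divisor` times the
#' as-consumed concentration.
#'
#' @param config a [synth_config()] object.
#' @param seed optional RNG seed (overrides `config$seed`).
#' @return A data frame of concentration records with columns `agency`,
#'   `category`, `product_id`, `status` (one of `detected_quantified`,
#'   `detected_censored`, `not_detected`), `value_ppm` (present iff
#'   quantified) and `concentrated_flag`.
#' @export
#' @examples
#' cfg <- synth_config()
#' sv <- generate_concentration_survey(cfg, seed = 1)
#' table(sv$status)
generate_concentration_survey <- function(config, seed = NULL) {
  validate_synth_config(config)
  set_seed_if(seed %||% config$seed)
  cats <- food_categories()
  K <- length(config$bin_edges)
  lower <- config$bin_edges
  upper <- c(config$bin_edges[-1], config$bin_cap)

  out <- vector("list", length(cats) * 2L)
  idx <- 0L
  for (cat in cats) {
    p_kboh <- config$true_p_d[[cat]]
    ## exp(beta) is the TFDA/KBOH odds ratio for NON-detection
    odds_nd_kboh <- (1 - p_kboh) / max(p_kboh, 1e-12)
    odds_nd_tfda <- exp(config$true_beta[[cat]]) * odds_nd_kboh
    p_tfda <- 1 / (1 + odds_nd_tfda)
    for (ag in agencies()) {
      n <- config$n_products[cat, ag]
      if (n == 0) next
      p <- if (ag == "KBOH") p_kboh else p_tfda
      det <- stats::runif(n) < p
      value <- rep(NA_real_, n)
      status <- ifelse(det, "detected_quantified", "not_detected")
      conc_flag <- rep(FALSE, n)
      nd <- sum(det)
      if (nd > 0) {
        w <- matrix(config$bin_weights[cat, ], nrow = nd, ncol = K,
                    byrow = TRUE)
        bin <- sample_bins(w)
        y <- rtlnorm(nd, config$bin_log_means[bin], config$bin_log_sds[bin],
                     lower[bin], upper[bin])
        if (cat == "juice_beverages" && config$juice_concentrate_frac > 0) {
          cc <- stats::runif(nd) < config$juice_concentrate_frac
          y[cc] <- y[cc] * config$juice_divisor
          conc_flag[det][cc] <- TRUE
        }
        cens <- stats::runif(nd) < config$censor_fraction
        value[det] <- ifelse(cens, NA_real_, y)
        status[det][cens] <- "detected_censored"
      }
      idx <- idx + 1L
      out[[idx]] <- data.frame(
        agency = ag, category = cat,
        product_id = sprintf("%s_%s_%04d", substr(ag, 1, 1), cat, seq_len(n)),
        status = status, value_ppm = value, concentrated_flag = conc_flag,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out[seq_len(idx)])
}
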
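#' Configuration of the synthetic-data generator
#'
#' Builds and validates the configuration object describing the "stated
#' world" from which synthetic concentration surveys, cohorts,
#' questionnaires, self-reports and urine panels are generated. Defaults
#' reproduce the structure of the 2011 Taiwan DEHP incident data: survey
#' sizes per category and agency, category-level detection probabilities and
#' agency odds ratios close to the published estimates, a binned lognormal
#' concentration mixture spanning roughly 1 to several thousand ppm with a
#' 1-ppm screening level, roughly half of detected records reported only as
#' "> 1 ppm", a 237/13/97 children/adolescents/adults cohort, and spot-urine
#' metabolite panels with the published detection limits.
#'
#' @param n_products integer matrix (5 categories x 2 agencies) of survey
#'   sizes; defaults to the published agency totals.
#' @param true_p_d detection probability (concentration >= 1 ppm) in the
#'   KBOH (baseline) stratum, per category.
#' @param true_beta log non-detection odds ratio of TFDA relative to KBOH,
#'   per category.
#' @param bin_edges increasing ppm interval boundaries for the detected-food
#'   mixture; the first edge must be 1 (the screening level).
#' @param bin_cap upper truncation (ppm) of the last, nominally open-ended
#'   bin; keeps expected concentrations physically bounded.
#' @param bin_log_means,bin_log_sds lognormal parameters of each mixture bin.
#' @param bin_weights matrix (5 x K) of true mixture weights per category;
#'   rows sum to 1.
#' @param true_p1_frac true fraction of the non-detected mass lying in
#'   (0, 1) ppm rather than at exactly 0.
#' @param censor_fraction fraction of detected records carrying no numeric
#'   value (reported only as "> 1 ppm").
#' @param juice_concentrate_frac fraction of detected juice records that are
#'   concentrates (measured value is `juice_divisor` times the as-consumed
#'   concentration).
#' @param juice_divisor dilution ratio for concentrated juice (default 7).
#' @param n_children,n_adolescents,n_adults cohort sizes by age group.
#' @param n_missing_urine,n_negligible deterministic counts, per age group
#'   (children, adolescents, adults), of participants lacking a urine sample
#'   or reporting negligible consumption frequency; both are excluded from
#'   AvDI estimation.
#' @param p_exposed matrix (5 x 3) of questionnaire response probabilities
#'   (yes / unsure / no) per category.
#' @param p_freq,p_dur probabilities of the weekly-frequency categories
#'   (<=2, 3-5, >=6 times/week) and duration categories (<0.5, 0.5-1, 1-2,
#'   >2 years).
#' @param p_self_report probability, per age group, that a participant
#'   provides a self-reported exposure history.
#' @param p_missing_field probability that a self-report amount or frequency
#'   field is missing (missing completely at random).
#' @param bottle_ml standard bottled/cup drink volume (ml).
#' @param jam_mean_g,jam_sd_g normal parameters of the daily fruit-jam
#'   consumption amount (g), truncated at 0.
#' @param supplement_meanlog,supplement_sdlog lognormal parameters of the
#'   supplement dosage per occasion (g).
#' @param urine_log_mean,urine_log_sd lognormal parameters (log ug/L) of the
#'   MEHP, MEHHP and MEOHP spot-urine concentrations.
#' @param creatinine_meanlog,creatinine_sdlog lognormal parameters of urinary
#'   creatinine (g/L).
#' @param lod detection limits (ug/L = ng/mL) of the three metabolites.
#' @param lag_days_range range of the clinic-visit lag (days after
#'   2011-05-31); visits took place 14 to 21 months after the incident.
#' @param seed optional RNG seed stored with the configuration.
#'
#' @return An object of class `synth_config` (a validated list).
#' @export
#' @examples
#' cfg <- synth_config(n_children = 20, n_adolescents = 2, n_adults = 8)
#' cfg$n_children
synth_config <- function(n_products = NULL,
                         true_p_d = c(0.058, 0.042, 0.014, 0.041, 0.105),
                         true_beta = log(c(44.1, 0.8, 6.3, 5.6, 4.9)),
                         bin_edges = c(1, 10, 100),
                         bin_cap = 5000,
                         bin_log_means = c(1.1, 3.4, 5.7),
                         bin_log_sds = c(0.5, 0.5, 0.7),
                         bin_weights = NULL,
                         true_p1_frac = 0.02,
                         censor_fraction = 0.5,
                         juice_concentrate_frac = 0.3,
                         juice_divisor = 7,
                         n_children = 237, n_adolescents = 13, n_adults = 97,
                         n_missing_urine = c(10, 0, 1),
                         n_negligible = c(0, 1, 1),
                         p_exposed = NULL,
                         p_freq = c(0.5, 0.3, 0.2),
                         p_dur = c(0.25, 0.3, 0.25, 0.2),
                         p_self_report = c(0.90, 0.80, 0.76),
                         p_missing_field = 0.1,
                         bottle_ml = 350,
                         jam_mean_g = 15, jam_sd_g = 5,
                         supplement_meanlog = log(2), supplement_sdlog = 0.5,
                         urine_log_mean = log(c(5, 20, 15)),
                         urine_log_sd = c(0.9, 0.9, 0.9),
                         creatinine_meanlog = log(1), creatinine_sdlog = 0.35,
                         lod = c(mehp = 0.7, mehhp = 0.3, meohp = 0.3),
                         lag_days_range = c(440, 630),
                         seed = NULL) {
  cats <- food_categories()
  K <- length(bin_edges)
  if (is.null(n_products)) {
    pub <- published_survey_counts()
    n_products <- matrix(pub$total, nrow = 5, ncol = 2, byrow = TRUE,
                         dimnames = list(cats, agencies()))
  }
  if (is.null(bin_weights)) {
    bin_weights <- rbind(
      sport_drinks    = c(0.70, 0.28, 0.02),
      tea_drinks      = c(0.60, 0.37, 0.03),
      juice_beverages = c(0.50, 0.40, 0.10),
      fruit_jam       = c(0.30, 0.40, 0.30),
      supplements     = c(0.40, 0.45, 0.15)
    )[, seq_len(K), drop = FALSE]
    bin_weights <- bin_weights / rowSums(bin_weights)
  }
  if (is.null(p_exposed)) {
    p_exposed <- rbind(
      sport_drinks    = c(0.15, 0.50, 0.35),
      tea_drinks      = c(0.15, 0.50, 0.35),
      juice_beverages = c(0.15, 0.50, 0.35),
      fruit_jam       = c(0.10, 0.45, 0.45),
      supplements     = c(0.55, 0.20, 0.25)
    )
  }
  colnames(p_exposed) <- c("yes", "unsure", "no")
  rownames(bin_weights) <- rownames(p_exposed) <- cats

  cfg <- list(
    n_products = n_products,
    true_p_d = stats::setNames(true_p_d, cats),
    true_beta = stats::setNames(true_beta, cats),
    bin_edges = bin_edges, bin_cap = bin_cap,
    bin_log_means = bin_log_means, bin_log_sds = bin_log_sds,
    bin_weights = bin_weights,
    true_p1_frac = true_p1_frac,
    censor_fraction = censor_fraction,
    juice_concentrate_frac = juice_concentrate_frac,
    juice_divisor = juice_divisor,
    n_children = n_children, n_adolescents = n_adolescents,
    n_adults = n_adults,
    n_missing_urine = stats::setNames(n_missing_urine,
                                      c("children", "adolescents", "adults")),
    n_negligible = stats::setNames(n_negligible,
                                   c("children", "adolescents", "adults")),
    p_exposed = p_exposed,
    p_freq = stats::setNames(p_freq, c("le2", "3to5", "ge6")),
    p_dur = stats::setNames(p_dur, c("lt6m", "6to12m", "1to2y", "gt2y")),
    p_self_report = stats::setNames(p_self_report,
                                    c("children", "adolescents", "adults")),
    p_missing_field = p_missing_field,
    bottle_ml = bottle_ml, jam_mean_g = jam_mean_g, jam_sd_g = jam_sd_g,
    supplement_meanlog = supplement_meanlog,
    supplement_sdlog = supplement_sdlog,
    urine_log_mean = stats::setNames(urine_log_mean,
                                     c("mehp", "mehhp", "meohp")),
    urine_log_sd = stats::setNames(urine_log_sd,
                                   c("mehp", "mehhp", "meohp")),
    creatinine_meanlog = creatinine_meanlog,
    creatinine_sdlog = creatinine_sdlog,
    lod = lod,
    lag_days_range = lag_days_range,
    seed = seed
  )
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  if (!inherits(cfg, "synth_config")) stop("not a synth_config object")
  check_probs(cfg$true_p_d, "true_p_d")
  check_probs(cfg$true_p1_frac, "true_p1_frac")
  check_probs(cfg$censor_fraction, "censor_fraction")
  check_probs(cfg$juice_concentrate_frac, "juice_concentrate_frac")
  check_probs(cfg$p_exposed, "p_exposed")
  check_probs(cfg$p_freq, "p_freq")
  check_probs(cfg$p_dur, "p_dur")
  check_probs(cfg$p_self_report, "p_self_report")
  check_probs(cfg$p_missing_field, "p_missing_field")
  if (any(abs(rowSums(cfg$p_exposed) - 1) > 1e-8)) {
    stop("rows of p_exposed must sum to 1", call. = FALSE)
  }
  e <- cfg$bin_edges
  if (length(e) < 1 || e[1] != 1 || (length(e) > 1 && any(diff(e) <= 0))) {
    stop("bin_edges must be strictly increasing with first edge = 1 ppm",
         call. = FALSE)
  }
  if (cfg$bin_cap <= e[length(e)]) {
    stop("bin_cap must exceed the last bin edge", call. = FALSE)
  }
  sizes <- c(cfg$n_children, cfg$n_adolescents, cfg$n_adults)
  if (any(sizes < 0) || any(sizes != round(sizes))) {
    stop("cohort sizes must be non-negative integers", call. = FALSE)
  }
  if (any(cfg$n_missing_urine > sizes) || any(cfg$n_negligible > sizes)) {
    stop("exclusion counts cannot exceed cohort sizes", call. = FALSE)
  }
  if (length(cfg$bin_log_means) != length(cfg$bin_edges) ||
      length(cfg$bin_log_sds) != length(cfg$bin_edges) ||
      ncol(cfg$bin_weights) != length(cfg$bin_edges)) {
    stop("bin parameter lengths must match the number of bins", call. = FALSE)
  }
  if (any(cfg$bin_log_sds < 0)) stop("bin_log_sds must be >= 0", call. = FALSE)
  invisible(cfg)
}

#' @export
print.synth_config <- function(x, ...) {
  cat("Synthetic-data configuration\n")
  cat(sprintf("  survey: %d records over %d categories x 2 agencies\n",
              sum(x$n_products), nrow(x$n_products)))
  cat(sprintf("  mixture: %d bins on edges [%s] ppm (cap %g)\n",
              length(x$bin_edges),
              paste(x$bin_edges, collapse = ", "), x$bin_cap))
  cat(sprintf("  cohort: %d children, %d adolescents, %d adults\n",
              x$n_children, x$n_adolescents, x$n_adults))
  invisible(x)
}
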
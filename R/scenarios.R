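#' Defaults governing dose reconstruction
#'
#' Collects the tunable constants of the questionnaire/self-report dose
#' reconstruction: the standard bottled-drink volume, the fruit-jam amount
#' distribution, the supplement dosage fallback, the weekly-frequency
#' midpoints (1, 4, 7 times/week for the <=2, 3-5, >=6 categories) and
#' duration midpoints (3, 9, 18 months; the open-ended > 2 y class capped
#' at 24 months), the growth-rate-coefficient noise (CV 0.16, truncated
#' below at 0.5), and cohort means of reported amounts/frequencies used for
#' mean-imputation of missing self-report fields.
#'
#' @param bottle_ml standard volume of a bottled/cup drink (ml).
#' @param jam_mean_g,jam_sd_g normal parameters of the daily jam amount (g),
#'   truncated at 0.
#' @param supplement_g fallback supplement dosage per occasion (g) when no
#'   cohort mean is available.
#' @param freq_midpoints weekly-frequency midpoints per frequency category.
#' @param dur_midpoints_m duration midpoints in months per duration category.
#' @param days_per_month days per month used to convert durations.
#' @param grc_cv coefficient of variation of the stochastic GRC.
#' @param grc_floor lower truncation of GRC draws.
#' @param cohort_means optional list as returned by [cohort_report_means()].
#' @return A list of class `recon_defaults`.
#' @export
reconstruction_defaults <- function(bottle_ml = 350,
                                    jam_mean_g = 15, jam_sd_g = 5,
                                    supplement_g = 2,
                                    freq_midpoints = c(le2 = 1, "3to5" = 4,
                                                       ge6 = 7),
                                    dur_midpoints_m = c(lt6m = 3,
                                                        "6to12m" = 9,
                                                        "1to2y" = 18,
                                                        gt2y = 24),
                                    days_per_month = 365.25 / 12,
                                    grc_cv = 0.16, grc_floor = 0.5,
                                    cohort_means = NULL) {
  structure(list(bottle_ml = bottle_ml, jam_mean_g = jam_mean_g,
                 jam_sd_g = jam_sd_g, supplement_g = supplement_g,
                 freq_midpoints = freq_midpoints,
                 dur_midpoints_m = dur_midpoints_m,
                 days_per_month = days_per_month,
                 grc_cv = grc_cv, grc_floor = grc_floor,
                 cohort_means = cohort_means),
            class = "recon_defaults")
}

#' Cohort means of reported self-report fields
#'
#' Per-category means of the non-missing reported consumption amounts and
#' weekly frequencies, used to impute missing self-report fields.
#'
#' @param self_reports data frame of self-report entries with columns
#'   `category`, `amount`, `freq_per_week`.
#' @return List with named numeric vectors `amount` and `freq_per_week`.
#' @export
cohort_report_means <- function(self_reports) {
  if (is.null(self_reports) || nrow(self_reports) == 0) {
    return(list(amount = numeric(0), freq_per_week = numeric(0)))
  }
  mean_by <- function(v) {
    tapply(v, self_reports$category, function(x) {
      x <- x[!is.na(x)]
      if (length(x)) mean(x) else NA_real_
    })
  }
  list(amount = mean_by(self_reports$amount),
       freq_per_week = mean_by(self_reports$freq_per_week))
}

## Default consumption amount for a category (mean, sd); drinks use the
## standard bottle, jam is stochastic, supplements fall back to the cohort
## average dosage.
default_amount <- function(category, defaults) {
  cm <- defaults$cohort_means$amount
  if (category %in% c("sport_drinks", "tea_drinks", "juice_beverages")) {
    c(mean = defaults$bottle_ml, sd = 0)
  } else if (category == "fruit_jam") {
    c(mean = defaults$jam_mean_g, sd = defaults$jam_sd_g)
  } else {
    amt <- if (!is.null(cm) && "supplements" %in% names(cm) &&
               is.finite(cm[["supplements"]])) {
      cm[["supplements"]]
    } else defaults$supplement_g
    c(mean = amt, sd = 0)
  }
}

#' Resolve exposure scenarios for one participant
#'
#' Combines the questionnaire response and any self-report entries into one
#' exposure scenario per consumption, applying the precedence and imputation
#' rules: a category with a self-report uses the self-report (the
#' questionnaire contribution for that category is zeroed); otherwise the
#' questionnaire response drives the scenario, with the concentration drawn
#' later according to the belief (yes: tainted mixture, unsure: overall
#' category distribution, no: zero), weekly frequencies mapped to the
#' category midpoints (converted to times/day), durations mapped to the
#' midpoint months, and amounts set to the category defaults. Missing
#' self-report amounts or frequencies are imputed with the cohort means of
#' the reported values.
#'
#' @param resp questionnaire response (see [score_questionnaire()]).
#' @param reports data frame of self-report entries for this participant
#'   (columns `category`, `product`, `amount`, `freq_per_week`,
#'   `duration_days`, `simultaneous`), or `NULL`.
#' @param defaults a [reconstruction_defaults()] object.
#' @return A data frame of scenarios: `category`, `source`
#'   (`questionnaire`/`self_report`/`none`), `belief`, `amount_mean`,
#'   `amount_sd`, `ef_per_day`, `ed_days`, `simultaneous`.
#' @export
resolve_scenarios <- function(resp, reports = NULL,
                              defaults = reconstruction_defaults()) {
  cats <- food_categories()
  if (!is.null(reports) && nrow(reports) > 0) {
    bad <- setdiff(unique(reports$category), cats)
    if (length(bad)) {
      stop(sprintf("self-report references unknown category: %s",
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  rows <- list()
  for (cat in cats) {
    has_sf <- !is.null(reports) && nrow(reports) > 0 &&
      any(reports$category == cat)
    if (has_sf) {
      sub <- reports[reports$category == cat, , drop = FALSE]
      for (i in seq_len(nrow(sub))) {
        amt <- sub$amount[i]
        if (is.na(amt)) {
          cm <- defaults$cohort_means$amount
          amt <- if (!is.null(cm) && cat %in% names(cm) &&
                     is.finite(cm[[cat]])) cm[[cat]]
          else default_amount(cat, defaults)[["mean"]]
        }
        fq <- sub$freq_per_week[i]
        if (is.na(fq)) {
          cm <- defaults$cohort_means$freq_per_week
          fq <- if (!is.null(cm) && cat %in% names(cm) &&
                    is.finite(cm[[cat]])) cm[[cat]]
          else mean(defaults$freq_midpoints)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          category = cat, source = "self_report", belief = "yes",
          amount_mean = amt, amount_sd = 0, ef_per_day = fq / 7,
          ed_days = sub$duration_days[i],
          simultaneous = isTRUE(sub$simultaneous[i]),
          stringsAsFactors = FALSE
        )
      }
    } else {
      r <- resp[resp$category == cat, , drop = FALSE]
      belief <- if (nrow(r)) r$exposed[1] else "no"
      if (belief == "no") {
        rows[[length(rows) + 1L]] <- data.frame(
          category = cat, source = "none", belief = "no",
          amount_mean = 0, amount_sd = 0, ef_per_day = 0, ed_days = 0,
          simultaneous = TRUE, stringsAsFactors = FALSE
        )
      } else {
        amt <- default_amount(cat, defaults)
        ef <- defaults$freq_midpoints[[r$freq_cat[1]]] / 7
        ed <- defaults$dur_midpoints_m[[r$dur_cat[1]]] * defaults$days_per_month
        rows[[length(rows) + 1L]] <- data.frame(
          category = cat, source = "questionnaire", belief = belief,
          amount_mean = amt[["mean"]], amount_sd = amt[["sd"]],
          ef_per_day = ef, ed_days = ed, simultaneous = TRUE,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, rows)
}

#' Averaging time of exposure
#'
#' For questionnaire scenarios, the averaging time AT (days) is the maximum
#' exposure duration over the five categories. For self-report scenarios,
#' durations of foods consumed at discontinuous time periods are summed,
#' while simultaneously consumed foods contribute through the maximum
#' duration.
#'
#' @param scenarios data frame from [resolve_scenarios()].
#' @param source `"questionnaire"` or `"self_report"`.
#' @return AT in days (0 when no scenario of that source has exposure).
#' @export
compute_averaging_time <- function(scenarios,
                                   source = c("questionnaire",
                                              "self_report")) {
  source <- match.arg(source)
  sub <- scenarios[scenarios$source == source, , drop = FALSE]
  if (nrow(sub) == 0) return(0)
  if (any(sub$ed_days < 0)) stop("negative durations", call. = FALSE)
  if (source == "questionnaire") return(max(sub$ed_days, 0))
  disc <- sub$ed_days[!sub$simultaneous]
  sim <- sub$ed_days[sub$simultaneous]
  sum(disc) + if (length(sim)) max(sim) else 0
}

#' Growth-adjusted body weight at the incident end
#'
#' Back-projects a participant's clinic-visit body weight to the end of the
#' incident using the growth-rate coefficient: `BW_b = BW / gamma`. The
#' point GRC is the ratio of reference median weights at the current age and
#' at `age - lag`; for adults (age >= 18) gamma = 1. Stochastic draws use
#' gamma ~ Normal(gamma, (cv * gamma)^2), truncated below at `floor`.
#'
#' @param participant list with `age`, `sex`, `weight_kg`, `lag_days`.
#' @param ref a [generate_growth_reference()] table.
#' @param n_draws number of stochastic draws; `n_draws = 1` with `cv = 0`
#'   gives the deterministic point adjustment.
#' @param cv coefficient of variation of the GRC draws (default 0.16).
#' @param floor lower truncation of the GRC draws.
#' @param seed optional RNG seed.
#' @return List with `gamma` (point GRC), `bw_b` (vector of draws, kg).
#' @export
#' @examples
#' ref <- generate_growth_reference()
#' p <- list(age = 5, sex = "male", weight_kg = 20,
#'           lag_days = 1.5 * 365.25)
#' growth_adjusted_weight(p, ref, n_draws = 1, cv = 0)$bw_b  # ~16.7 kg
growth_adjusted_weight <- function(participant, ref, n_draws = 1, cv = 0.16,
                                   floor = 0.5, seed = NULL) {
  set_seed_if(seed)
  gamma <- growth_rate_coefficient(ref, participant$sex, participant$age,
                                   participant$lag_days / 365.25)
  if (cv <= 0 || gamma == 1) {
    g <- rep(gamma, n_draws)
  } else {
    g <- rtnorm_lower(n_draws, gamma, cv * gamma, floor)
  }
  list(gamma = gamma, bw_b = participant$weight_kg / g)
}

#' Average daily intake from exposure scenarios
#'
#' Evaluates the intake equation
#' `AvDI = sum_i Y_i * M_i * EF_i * ED_i / (AT * BW_b)` over the scenario
#' rows. The unit contract is ppm (mg/L for liquids, mg/kg for solids)
#' times ml (or g), which yields micrograms directly, so the result is in
#' ug per kg body weight per day.
#'
#' @param scenarios data frame with columns `y` (ppm), `amount` (ml or g),
#'   `ef_per_day`, `ed_days`.
#' @param bw_b body weight at the incident end (kg, > 0).
#' @param at averaging time (days); must be > 0 when any exposure is
#'   positive.
#' @return AvDI in ug/kg_bw/day (0 when all exposures are zero).
#' @export
#' @examples
#' sc <- data.frame(y = 2, amount = 350, ef_per_day = 1, ed_days = 180)
#' avdi_intake(sc, bw_b = 16.7, at = 180)  # ~41.9
avdi_intake <- function(scenarios, bw_b, at) {
  if (bw_b <= 0) stop("BW_b must be positive", call. = FALSE)
  num <- sum(scenarios$y * scenarios$amount * scenarios$ef_per_day *
               scenarios$ed_days)
  if (num == 0) return(0)
  if (at <= 0) stop("AT must be positive when exposure is positive",
                    call. = FALSE)
  num / (at * bw_b)
}
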
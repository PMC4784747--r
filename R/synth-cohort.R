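## Truncated normal on [lo, hi] via inverse CDF.
rtnorm_range <- function(n, mean, sd, lo, hi) {
  p1 <- stats::pnorm(lo, mean, sd); p2 <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, p1, p2), mean, sd)
}

## True category-level expected concentrations implied by a synth_config.
true_expected_concentrations <- function(config) {
  lower <- config$bin_edges
  upper <- c(config$bin_edges[-1], config$bin_cap)
  m <- trunc_lnorm_mean(config$bin_log_means, config$bin_log_sds, lower,
                        upper)
  e_y <- as.vector(config$bin_weights %*% m)
  p_d <- config$true_p_d
  p_1 <- (1 - p_d) * config$true_p1_frac
  e_c <- ec_composition(p_d, e_y, p_1)
  data.frame(category = food_categories(), p_d = p_d, p_1 = p_1,
             e_y = e_y, e_c = e_c, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic study cohort with known ground truth
#'
#' Simulates the participant streams of an incident follow-up study:
#' demographics (children < 12 y, adolescents 12-18 y, adults >= 18 y, with
#' heights, weights and clinic-visit lags), five-category food-frequency
#' questionnaires, self-reported exposure histories (with
#' missing-completely-at-random amount/frequency fields), and spot-urine
#' metabolite panels with below-LOD flags at the published detection limits
#' (0.7, 0.3, 0.3 ng/mL for MEHP, MEHHP, MEOHP). Deterministic numbers of
#' participants per age group lack a urine sample or have negligible
#' consumption frequency, reproducing the study's eligibility arithmetic.
#'
#' Ground truth stores, for every participant, the true intake components
#' implied by the true scenario parameters: dietary concentrations enter at
#' the true category-level expected values (`E(Y)` of the true mixture for
#' certain exposure and self-reports, `E(C)` for unsure exposure), amounts,
#' frequencies and durations at their true (pre-missingness) values, and
#' body weight back-projected with the point GRC. `AvDI_ALL` is the sum of
#' its components by construction. The background component is the
#' deterministic urinary back-calculation of the stored sample.
#'
#' @param config a [synth_config()].
#' @param seed optional RNG seed (overrides `config$seed`).
#' @return A list with data frames `participants`, `questionnaires`,
#'   `self_reports`, `urine`, `ground_truth`, plus `true_params` (the true
#'   category-level concentration parameters) and the `config`.
#' @export
#' @examples
#' cfg <- synth_config(n_children = 30, n_adolescents = 3, n_adults = 12,
#'                     n_missing_urine = c(2, 0, 1),
#'                     n_negligible = c(0, 0, 0))
#' coh <- generate_cohort(cfg, seed = 7)
#' nrow(coh$participants)  # 45
generate_cohort <- function(config, seed = NULL) {
  validate_synth_config(config)
  sizes <- c(children = config$n_children, adolescents = config$n_adolescents,
             adults = config$n_adults)
  if (sum(sizes) == 0) stop("empty cohort: all group sizes are zero",
                            call. = FALSE)
  set_seed_if(seed %||% config$seed)
  growth <- generate_growth_reference()

  ## ---- participants -------------------------------------------------------
  n_total <- sum(sizes)
  age_group <- rep(names(sizes), times = sizes)
  age <- numeric(n_total)
  age[age_group == "children"] <- rtnorm_range(sizes[["children"]], 6, 2.2,
                                               3, 11.9)
  age[age_group == "adolescents"] <- stats::runif(sizes[["adolescents"]],
                                                  12, 17.9)
  age[age_group == "adults"] <- rtnorm_range(sizes[["adults"]], 40, 10,
                                             18, 75)
  sex <- sample(c("male", "female"), n_total, replace = TRUE,
                prob = c(0.55, 0.45))
  height <- ifelse(age < 18,
                   pmin(72 + 6 * age + stats::rnorm(n_total, 0, 4), 185),
                   ifelse(sex == "male", 172, 160) +
                     stats::rnorm(n_total, 0, 6))
  med_w <- vapply(seq_len(n_total), function(i) {
    if (age[i] < 18) lookup_median_weight(growth, sex[i], age[i])
    else if (sex[i] == "male") 68 else 56
  }, numeric(1))
  weight <- med_w * exp(stats::rnorm(n_total, 0, 0.12))
  lag_days <- stats::runif(n_total, config$lag_days_range[1],
                           config$lag_days_range[2])

  participants <- data.frame(
    participant_id = sprintf("P%04d", seq_len(n_total)),
    age_group = age_group, age = age, sex = sex,
    height_cm = height, weight_kg = weight, lag_days = lag_days,
    has_urine = TRUE, negligible_freq = FALSE,
    stringsAsFactors = FALSE
  )
  for (g in names(sizes)) {
    idx <- which(participants$age_group == g)
    nm <- config$n_missing_urine[[g]]
    if (nm > 0) participants$has_urine[sample(idx, nm)] <- FALSE
    pool <- idx[participants$has_urine[idx]]
    ng <- config$n_negligible[[g]]
    if (ng > 0) participants$negligible_freq[sample(pool, ng)] <- TRUE
  }

  ## ---- questionnaires and self-reports ------------------------------------
  cats <- food_categories()
  qn_rows <- vector("list", n_total)
  sf_rows <- list()
  for (i in seq_len(n_total)) {
    pid <- participants$participant_id[i]
    grp <- participants$age_group[i]
    if (participants$negligible_freq[i]) {
      qn_rows[[i]] <- data.frame(participant_id = pid, category = cats,
                                 exposed = "no", freq_cat = NA_character_,
                                 dur_cat = NA_character_,
                                 stringsAsFactors = FALSE)
      next
    }
    exposed <- vapply(cats, function(cat) {
      sample(c("yes", "unsure", "no"), 1, prob = config$p_exposed[cat, ])
    }, character(1))
    has_sf <- stats::runif(1) < config$p_self_report[[grp]]
    sf_cats <- character(0)
    if (has_sf) {
      if (stats::runif(1) < 0.95) sf_cats <- "supplements"
      if (stats::runif(1) < 0.15) {
        sf_cats <- c(sf_cats, sample(setdiff(cats, "supplements"), 1))
      }
    }
    exposed[sf_cats] <- "yes"
    freq_cat <- ifelse(exposed == "no", NA_character_,
                       sample(names(config$p_freq), length(cats),
                              replace = TRUE, prob = config$p_freq))
    dur_cat <- ifelse(exposed == "no", NA_character_,
                      sample(names(config$p_dur), length(cats),
                             replace = TRUE, prob = config$p_dur))
    qn_rows[[i]] <- data.frame(participant_id = pid, category = cats,
                               exposed = exposed, freq_cat = freq_cat,
                               dur_cat = dur_cat, stringsAsFactors = FALSE)
    for (cat in sf_cats) {
      amount_true <- if (cat == "supplements") {
        stats::rlnorm(1, config$supplement_meanlog, config$supplement_sdlog)
      } else if (cat == "fruit_jam") {
        rtnorm_lower(1, config$jam_mean_g, config$jam_sd_g, 0)
      } else config$bottle_ml
      freq_true <- if (cat == "supplements") {
        sample(c(2, 3, 5, 7, 14), 1, prob = c(0.2, 0.2, 0.2, 0.3, 0.1))
      } else sample(c(1, 2, 3, 5, 7), 1, prob = c(0.3, 0.25, 0.2, 0.15, 0.1))
      n_periods <- if (stats::runif(1) < 0.7) 1L else 2L
      duration <- sum(round(stats::runif(n_periods, 60, 540)))
      simultaneous <- n_periods == 1L || stats::runif(1) < 0.4
      sf_rows[[length(sf_rows) + 1L]] <- data.frame(
        participant_id = pid, category = cat,
        product = paste0(cat, "_brand"),
        amount_true = amount_true, freq_true = freq_true,
        amount = ifelse(stats::runif(1) < config$p_missing_field,
                        NA_real_, amount_true),
        freq_per_week = ifelse(stats::runif(1) < config$p_missing_field,
                               NA_real_, freq_true),
        duration_days = duration, simultaneous = simultaneous,
        stringsAsFactors = FALSE
      )
    }
  }
  questionnaires <- do.call(rbind, qn_rows)
  self_reports <- if (length(sf_rows)) do.call(rbind, sf_rows) else
    data.frame(participant_id = character(0), category = character(0),
               product = character(0), amount_true = numeric(0),
               freq_true = numeric(0), amount = numeric(0),
               freq_per_week = numeric(0), duration_days = numeric(0),
               simultaneous = logical(0))

  ## ---- urine panels -------------------------------------------------------
  with_urine <- which(participants$has_urine)
  nu <- length(with_urine)
  draw_met <- function(m) stats::rlnorm(nu, config$urine_log_mean[[m]],
                                        config$urine_log_sd[[m]])
  mehp <- draw_met("mehp"); mehhp <- draw_met("mehhp")
  meohp <- draw_met("meohp")
  lod <- config$lod
  urine <- data.frame(
    participant_id = participants$participant_id[with_urine],
    mehp_ugL = pmax(mehp, lod[["mehp"]]),
    mehhp_ugL = pmax(mehhp, lod[["mehhp"]]),
    meohp_ugL = pmax(meohp, lod[["meohp"]]),
    mehp_below_lod = mehp < lod[["mehp"]],
    mehhp_below_lod = mehhp < lod[["mehhp"]],
    meohp_below_lod = meohp < lod[["meohp"]],
    creatinine_gL = stats::rlnorm(nu, config$creatinine_meanlog,
                                  config$creatinine_sdlog),
    stringsAsFactors = FALSE
  )

  ## ---- ground truth -------------------------------------------------------
  true_params <- true_expected_concentrations(config)
  gt <- compute_ground_truth(participants, questionnaires, self_reports,
                             urine, true_params, config, growth)
  list(participants = participants, questionnaires = questionnaires,
       self_reports = self_reports, urine = urine, ground_truth = gt,
       true_params = true_params, config = config)
}

## True per-participant AvDI components from the true scenario parameters.
compute_ground_truth <- function(participants, questionnaires, self_reports,
                                 urine, true_params, config, growth) {
  supp_mean <- exp(config$supplement_meanlog + config$supplement_sdlog^2 / 2)
  defaults_true <- reconstruction_defaults(
    bottle_ml = config$bottle_ml, jam_mean_g = config$jam_mean_g,
    jam_sd_g = 0, supplement_g = supp_mean, grc_cv = 0
  )
  cref <- creatinine_reference()
  pk <- pk_constants()
  ey <- stats::setNames(true_params$e_y, true_params$category)
  ec <- stats::setNames(true_params$e_c, true_params$category)

  rows <- lapply(seq_len(nrow(participants)), function(i) {
    p <- as.list(participants[i, ])
    resp <- questionnaires[questionnaires$participant_id ==
                             p$participant_id, , drop = FALSE]
    rep_true <- self_reports[self_reports$participant_id ==
                               p$participant_id, , drop = FALSE]
    if (nrow(rep_true)) {  # use true (pre-missingness) fields
      rep_true$amount <- rep_true$amount_true
      rep_true$freq_per_week <- rep_true$freq_true
    }
    scen <- resolve_scenarios(resp, rep_true, defaults_true)
    scen$y <- ifelse(scen$source == "none", 0,
                     ifelse(scen$belief == "unsure", ec[scen$category],
                            ey[scen$category]))
    scen$amount <- scen$amount_mean
    at_qn <- compute_averaging_time(scen, "questionnaire")
    at_sf <- compute_averaging_time(scen, "self_report")
    bw_b <- growth_adjusted_weight(p, growth, n_draws = 1, cv = 0)$bw_b
    qn <- scen[scen$source == "questionnaire", , drop = FALSE]
    sf <- scen[scen$source == "self_report", , drop = FALSE]
    avdi_qn <- if (nrow(qn)) avdi_intake(qn, bw_b, max(at_qn, 1)) else 0
    avdi_sf <- if (nrow(sf)) avdi_intake(sf, bw_b, max(at_sf, 1)) else 0
    u <- urine[urine$participant_id == p$participant_id, , drop = FALSE]
    env <- if (nrow(u)) avdi_env(as.list(u[1, ]), p, cref, pk) else NA_real_
    data.frame(participant_id = p$participant_id, age_group = p$age_group,
               avdi_qn = avdi_qn, avdi_sf = avdi_sf, avdi_env = env,
               avdi_all = avdi_qn + avdi_sf + env, bw_b = bw_b,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
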
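#' Reconstruct the posterior intake distribution of one participant
#'
#' Produces joint posterior draws of the intake components for a single
#' participant: `AvDI_QN` (questionnaire categories, concentrations drawn
#' from the fitted category posteriors according to the exposure belief),
#' `AvDI_SF` (self-reported exposures, tainted-mixture concentrations),
#' `AvDI_ENV` (background intake back-calculated from the urine panel,
#' deterministic per sample), their sum `AvDI_ALL`, and the window-period
#' variants in which the averaging time is extended by the clinic-visit lag
#' (`AT* = AT + lag`) and the incident-date body weight `BW_b` is replaced
#' by the present weight `BW` for the dietary components; the background
#' component, which is defined from post-incident urine, is unchanged.
#' Growth-adjusted body-weight draws use the stochastic GRC.
#'
#' @param participant list/row with `participant_id`, `age`, `sex`,
#'   `weight_kg`, `height_cm`, `lag_days`.
#' @param resp questionnaire response for this participant.
#' @param reports self-report entries for this participant (may be `NULL`).
#' @param urine urine sample (see [molar_ue_sum()]); `NULL` marks the
#'   participant ineligible.
#' @param posteriors a `conc_fit` covering the exposed categories.
#' @param refs list with elements `growth` ([generate_growth_reference()]),
#'   `creatinine` ([creatinine_reference()]) and `pk` ([pk_constants()]).
#' @param defaults a [reconstruction_defaults()].
#' @param n_draws number of joint draws.
#' @param seed optional RNG seed.
#' @return An object of class `avdi_draws`: draws of all components plus
#'   the averaging times, body weights and eligibility flag.
#' @seealso [summarize_posterior()], [reconstruct_cohort()]
#' @export
reconstruct_participant <- function(participant, resp, reports, urine,
                                    posteriors,
                                    refs = list(
                                      growth = generate_growth_reference(),
                                      creatinine = creatinine_reference(),
                                      pk = pk_constants()),
                                    defaults = reconstruction_defaults(),
                                    n_draws = 2000, seed = NULL) {
  set_seed_if(seed)
  pid <- participant$participant_id %||% NA_character_
  if (is.null(urine)) {
    out <- list(participant_id = pid, eligible = FALSE, draws = NULL,
                reason = "no urine sample")
    class(out) <- "avdi_draws"
    return(out)
  }
  env <- avdi_env(urine, participant, ref = refs$creatinine, pk = refs$pk)
  scen <- resolve_scenarios(resp, reports, defaults)
  at_qn <- compute_averaging_time(scen, "questionnaire")
  at_sf <- compute_averaging_time(scen, "self_report")
  lag <- participant$lag_days %||% 0

  gw <- growth_adjusted_weight(participant, refs$growth, n_draws = n_draws,
                               cv = defaults$grc_cv,
                               floor = defaults$grc_floor)
  bw_b <- gw$bw_b
  bw <- participant$weight_kg

  num_qn <- numeric(n_draws)
  num_sf <- numeric(n_draws)
  for (i in seq_len(nrow(scen))) {
    s <- scen[i, ]
    if (s$source == "none" || s$ed_days <= 0 || s$ef_per_day <= 0) next
    y <- sample_concentration(posteriors, belief = s$belief, n = n_draws,
                              category = s$category)
    m <- if (s$amount_sd > 0) {
      rtnorm_lower(n_draws, s$amount_mean, s$amount_sd, 0)
    } else rep(s$amount_mean, n_draws)
    contrib <- y * m * s$ef_per_day * s$ed_days
    if (s$source == "questionnaire") num_qn <- num_qn + contrib
    else num_sf <- num_sf + contrib
  }
  safe_div <- function(num, at, w) {
    out <- numeric(length(num))
    pos <- num > 0
    if (any(pos)) {
      if (at <= 0) stop("AT must be positive when exposure is positive",
                        call. = FALSE)
      out[pos] <- num[pos] / (at * w[pos])
    }
    out
  }
  bw_vec <- rep(bw, n_draws)
  avdi_qn <- safe_div(num_qn, at_qn, bw_b)
  avdi_sf <- safe_div(num_sf, at_sf, bw_b)
  avdi_qn_w <- safe_div(num_qn, at_qn + lag, bw_vec)
  avdi_sf_w <- safe_div(num_sf, at_sf + lag, bw_vec)
  draws <- data.frame(
    avdi_qn = avdi_qn, avdi_sf = avdi_sf, avdi_env = rep(env, n_draws),
    avdi_all = avdi_qn + avdi_sf + env,
    avdi_qn_w = avdi_qn_w, avdi_sf_w = avdi_sf_w,
    avdi_all_w = avdi_qn_w + avdi_sf_w + env,
    bw_b = bw_b
  )
  out <- list(participant_id = pid, eligible = TRUE, draws = draws,
              at = c(qn = at_qn, sf = at_sf),
              at_star = c(qn = at_qn + lag, sf = at_sf + lag),
              bw = bw, gamma = gw$gamma, lag_days = lag)
  class(out) <- "avdi_draws"
  out
}

#' @export
print.avdi_draws <- function(x, ...) {
  if (!x$eligible) {
    cat(sprintf("Participant %s: ineligible (%s)\n", x$participant_id,
                x$reason))
    return(invisible(x))
  }
  s <- summarize_posterior(x)
  cat(sprintf("Participant %s: %d joint draws\n", x$participant_id,
              nrow(x$draws)))
  print(s, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Reconstruct intake distributions for a whole cohort
#'
#' Applies [reconstruct_participant()] to every participant of a cohort,
#' first computing the cohort means of reported self-report fields for
#' mean-imputation. Participants without a urine sample or flagged with
#' negligible consumption frequency are excluded (matching the incident
#' study's eligibility rules).
#'
#' @param cohort list as returned by [generate_cohort()] (elements
#'   `participants`, `questionnaires`, `self_reports`, `urine`), or the
#'   equivalent data frames read from file.
#' @param posteriors a `conc_fit`.
#' @param refs,defaults,n_draws as in [reconstruct_participant()].
#' @param seed optional master seed; participant-level seeds are derived
#'   from it.
#' @return A list with `results` (named list of `avdi_draws`), `summary`
#'   (data frame of per-participant posterior means of all components plus
#'   age group), and `eligibility` (counts of enrolled / excluded /
#'   eligible per age group).
#' @export
reconstruct_cohort <- function(cohort, posteriors,
                               refs = list(
                                 growth = generate_growth_reference(),
                                 creatinine = creatinine_reference(),
                                 pk = pk_constants()),
                               defaults = reconstruction_defaults(),
                               n_draws = 2000, seed = NULL) {
  parts <- cohort$participants
  defaults$cohort_means <- cohort_report_means(cohort$self_reports)
  results <- list()
  rows <- list()
  for (i in seq_len(nrow(parts))) {
    p <- as.list(parts[i, ])
    if (isTRUE(p$negligible_freq)) next
    urine_row <- cohort$urine[cohort$urine$participant_id ==
                                p$participant_id, , drop = FALSE]
    urine <- if (nrow(urine_row)) as.list(urine_row[1, ]) else NULL
    resp <- cohort$questionnaires[cohort$questionnaires$participant_id ==
                                    p$participant_id, , drop = FALSE]
    reports <- cohort$self_reports[cohort$self_reports$participant_id ==
                                     p$participant_id, , drop = FALSE]
    d <- reconstruct_participant(
      p, resp, reports, urine, posteriors, refs = refs,
      defaults = defaults, n_draws = n_draws,
      seed = if (is.null(seed)) NULL else seed + i
    )
    results[[p$participant_id]] <- d
    if (d$eligible) {
      cm <- colMeans(d$draws)
      rows[[length(rows) + 1L]] <- data.frame(
        participant_id = p$participant_id, age_group = p$age_group,
        avdi_qn = cm[["avdi_qn"]], avdi_sf = cm[["avdi_sf"]],
        avdi_env = cm[["avdi_env"]], avdi_all = cm[["avdi_all"]],
        avdi_all_w = cm[["avdi_all_w"]],
        stringsAsFactors = FALSE
      )
    }
  }
  summary <- if (length(rows)) do.call(rbind, rows) else
    data.frame(participant_id = character(0))
  groups <- c("children", "adolescents", "adults")
  enrolled <- vapply(groups, function(g) sum(parts$age_group == g),
                     integer(1))
  eligible <- vapply(groups, function(g)
    sum(summary$age_group == g), integer(1))
  list(results = results, summary = summary,
       eligibility = data.frame(age_group = groups, enrolled = enrolled,
                                eligible = eligible,
                                excluded = enrolled - eligible))
}
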
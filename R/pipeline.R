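#' Pipeline configuration
#'
#' Settings for an end-to-end reconstruction run: synthetic-mode generation
#' (or input CSV paths), MCMC settings, reconstruction defaults, number of
#' intake draws, output directory and master seed. All randomness flows
#' from the master seed, split per stage, so an identical configuration and
#' seed reproduce identical outputs.
#'
#' @param outdir output directory for run artifacts.
#' @param seed master RNG seed.
#' @param synthetic generate inputs with [generate_cohort()] /
#'   [generate_concentration_survey()] (`TRUE`) or read them from `inputs`.
#' @param synth a [synth_config()] used in synthetic mode.
#' @param mcmc an [mcmc_config()].
#' @param defaults a [reconstruction_defaults()].
#' @param n_draws joint intake draws per participant.
#' @param inputs named list of CSV paths (`survey`, `participants`,
#'   `questionnaires`, `self_reports`, `urine`) when `synthetic = FALSE`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir, seed = 1, synthetic = TRUE,
                            synth = synth_config(),
                            mcmc = mcmc_config(),
                            defaults = reconstruction_defaults(),
                            n_draws = 2000, inputs = NULL) {
  stopifnot(n_draws >= 1)
  structure(list(outdir = outdir, seed = as.integer(seed),
                 synthetic = synthetic, synth = synth, mcmc = mcmc,
                 defaults = defaults, n_draws = n_draws, inputs = inputs),
            class = "pipeline_config")
}

#' Validate pipeline input tables
#'
#' Schema and row-level checks of the five input CSV tables: required
#' columns, valid category/agency/status codes, non-negative concentrations,
#' positive creatinine, and the questionnaire invariant that frequency and
#' duration are present only when an exposure is reported. Problems are
#' reported with file and row, not thrown.
#'
#' @param paths named list of existing file paths (any of `survey`,
#'   `participants`, `questionnaires`, `self_reports`, `urine`).
#' @return A data frame (`file`, `row`, `severity`, `message`) with
#'   attribute `valid` (`TRUE` when no errors).
#' @export
validate_inputs <- function(paths) {
  issues <- list()
  note <- function(file, row, severity, message) {
    issues[[length(issues) + 1L]] <<- data.frame(
      file = file, row = row, severity = severity, message = message,
      stringsAsFactors = FALSE)
  }
  required <- list(
    survey = c("agency", "category", "product_id", "status", "value_ppm"),
    participants = c("participant_id", "age_group", "age", "sex",
                     "weight_kg"),
    questionnaires = c("participant_id", "category", "exposed", "freq_cat",
                       "dur_cat"),
    self_reports = c("participant_id", "category", "amount",
                     "freq_per_week", "duration_days"),
    urine = c("participant_id", "mehp_ugL", "mehhp_ugL", "meohp_ugL",
              "creatinine_gL")
  )
  for (nm in names(paths)) {
    if (!nm %in% names(required)) next
    if (!file.exists(paths[[nm]])) {
      note(nm, NA_integer_, "error", "file does not exist")
      next
    }
    df <- utils::read.csv(paths[[nm]], stringsAsFactors = FALSE)
    miss <- setdiff(required[[nm]], names(df))
    if (length(miss)) {
      note(nm, NA_integer_, "error",
           paste("missing required columns:", paste(miss, collapse = ", ")))
      next
    }
    if (nm == "survey") {
      bad <- which(!df$category %in% food_categories())
      for (r in bad) note(nm, r, "error", "unknown food category")
      bad <- which(!df$agency %in% agencies())
      for (r in bad) note(nm, r, "error", "unknown agency")
      bad <- which(df$status == "detected_quantified" &
                     (is.na(df$value_ppm) | df$value_ppm < 0))
      for (r in bad) note(nm, r, "error",
                          "quantified record with missing/negative value")
      bad <- which(!is.na(df$value_ppm) & df$value_ppm < 1 &
                     df$status == "detected_quantified")
      for (r in bad) note(nm, r, "warning",
                          "quantified value below the 1 ppm screen")
    }
    if (nm == "questionnaires") {
      bad <- which(df$exposed == "no" &
                     (!is.na(df$freq_cat) | !is.na(df$dur_cat)))
      for (r in bad) note(nm, r, "warning",
                          "frequency/duration given although exposed = no")
      bad <- which(!df$exposed %in% c("yes", "unsure", "no"))
      for (r in bad) note(nm, r, "error", "invalid exposed code")
    }
    if (nm == "urine") {
      bad <- which(is.na(df$creatinine_gL) | df$creatinine_gL <= 0)
      for (r in bad) note(nm, r, "error", "non-positive creatinine")
      for (col in c("mehp_ugL", "mehhp_ugL", "meohp_ugL")) {
        bad <- which(!is.na(df[[col]]) & df[[col]] < 0)
        for (r in bad) note(nm, r, "error",
                            paste("negative concentration in", col))
      }
    }
    if (nm == "self_reports") {
      bad <- which(!is.na(df$duration_days) & df$duration_days <= 0)
      for (r in bad) note(nm, r, "error", "non-positive duration")
    }
  }
  out <- if (length(issues)) do.call(rbind, issues) else
    data.frame(file = character(0), row = integer(0),
               severity = character(0), message = character(0))
  attr(out, "valid") <- !any(out$severity == "error")
  out
}

#' Run the end-to-end reconstruction pipeline
#'
#' Executes the full flow -- generate (or read) inputs, merge repeated
#' product measurements, fit the Bayesian concentration model, back-
#' calculate background intake, reconstruct per-participant intake
#' distributions, classify exposure groups and compare them -- and writes
#' all artifacts plus a JSON manifest (package version, seed, configuration
#' hash, per-file MD5 checksums, eligibility counts) to the output
#' directory. Identical configuration and seed give byte-identical
#' artifacts.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with the fitted model, reconstruction results,
#'   reporting tables and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$outdir, f)
  wcsv <- function(df, f) utils::write.csv(df, out(f), row.names = FALSE)

  ## stage seeds derived from the master seed
  seed_synth <- config$seed
  seed_fit <- config$seed + 1000L
  seed_recon <- config$seed + 2000L

  if (config$synthetic) {
    survey <- generate_concentration_survey(config$synth, seed = seed_synth)
    cohort <- generate_cohort(config$synth, seed = seed_synth + 1L)
    wcsv(survey, "concentration_survey.csv")
    wcsv(cohort$participants, "participants.csv")
    wcsv(cohort$questionnaires, "questionnaires.csv")
    wcsv(cohort$self_reports, "self_reports.csv")
    wcsv(cohort$urine, "urine.csv")
    wcsv(cohort$ground_truth, "ground_truth.csv")
  } else {
    paths <- config$inputs
    report <- validate_inputs(paths)
    if (!attr(report, "valid")) {
      bad <- report[report$severity == "error", ]
      stop(sprintf("invalid inputs: %s (file %s, row %s)", bad$message[1],
                   bad$file[1], bad$row[1]), call. = FALSE)
    }
    survey <- utils::read.csv(paths$survey, stringsAsFactors = FALSE)
    if (is.null(survey$concentrated_flag)) survey$concentrated_flag <- FALSE
    cohort <- list(
      participants = utils::read.csv(paths$participants,
                                     stringsAsFactors = FALSE),
      questionnaires = utils::read.csv(paths$questionnaires,
                                       stringsAsFactors = FALSE),
      self_reports = utils::read.csv(paths$self_reports,
                                     stringsAsFactors = FALSE),
      urine = utils::read.csv(paths$urine, stringsAsFactors = FALSE)
    )
    if (is.null(cohort$participants$negligible_freq)) {
      cohort$participants$negligible_freq <- FALSE
    }
  }

  merged <- merge_product_records(survey)
  mcmc <- config$mcmc
  mcmc$seed <- seed_fit
  fit <- fit_concentration_model(merged, mcmc = mcmc)
  fit_summary <- summary(fit)
  wcsv(as.data.frame(fit_summary), "posterior_summary.csv")

  recon <- reconstruct_cohort(cohort, fit, defaults = config$defaults,
                              n_draws = config$n_draws, seed = seed_recon)
  wcsv(recon$summary, "avdi_summary.csv")

  env_rows <- recon$summary[, c("participant_id", "avdi_env")]
  wcsv(env_rows, "avdi_env.csv")

  classified <- data.frame(
    age_group = recon$summary$age_group,
    group = classify_exposure(recon$summary$avdi_all)
  )
  classified_w <- data.frame(
    age_group = recon$summary$age_group,
    group = classify_exposure(recon$summary$avdi_all_w)
  )
  tab <- exposure_table(classified)
  tab_w <- exposure_table(classified_w)
  tab$window <- "without"; tab_w$window <- "with"
  table2 <- rbind(tab, tab_w)
  wcsv(table2, "table2.csv")

  chisq <- tryCatch({
    m <- as.matrix(tab[match(c("children", "adults"), tab$age_group),
                       c("low", "medium", "high", "very_high")])
    compare_groups_chisq(m)
  }, error = function(e) list(statistic = NA, df = NA, p_value = NA,
                              note = conditionMessage(e)))
  jsonlite::write_json(chisq, out("chisq.json"), auto_unbox = TRUE,
                       digits = NA)

  correlations <- component_correlations(recon$summary)
  wcsv(correlations, "correlations.csv")

  ## manifest with checksums for reproducibility checks
  files <- c("concentration_survey.csv", "participants.csv",
             "questionnaires.csv", "self_reports.csv", "urine.csv",
             "ground_truth.csv", "posterior_summary.csv", "avdi_summary.csv",
             "avdi_env.csv", "table2.csv", "chisq.json", "correlations.csv")
  files <- files[file.exists(file.path(config$outdir, files))]
  cfg_json <- jsonlite::toJSON(config[c("seed", "synthetic", "n_draws")],
                               auto_unbox = TRUE)
  tf <- tempfile(); writeLines(cfg_json, tf)
  manifest <- list(
    package = "dehpintake",
    version = as.character(utils::packageVersion("dehpintake")),
    seed = config$seed,
    config_hash = unname(tools::md5sum(tf)),
    eligibility = recon$eligibility,
    files = data.frame(
      file = files,
      md5 = unname(tools::md5sum(file.path(config$outdir, files))),
      stringsAsFactors = FALSE
    )
  )
  unlink(tf)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(list(fit = fit, recon = recon, table2 = table2, chisq = chisq,
                 correlations = correlations, manifest = manifest,
                 cohort = cohort))
}
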
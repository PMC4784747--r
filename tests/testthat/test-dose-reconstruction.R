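test_that("questionnaire scoring multiplies the subcategory points", {
  expect_equal(score_questionnaire(flat_response("yes", "ge6", "gt2y"))$total,
               1000)
  expect_equal(max(score_questionnaire(
    flat_response("yes", "ge6", "gt2y"))$per_category), 200)  # 10 x 5 x 4
  expect_equal(score_questionnaire(flat_response("no"))$total, 0)
  ## unsure, <= 2/week, < 0.5 y scores 1 x 1 x 1 = 1 per category
  expect_equal(score_questionnaire(
    flat_response("unsure", "le2", "lt6m"))$per_category[["tea_drinks"]], 1)
  ## mixed response
  r <- flat_response("no")
  r[r$category == "supplements", c("exposed", "freq_cat", "dur_cat")] <-
    list("yes", "3to5", "1to2y")
  expect_equal(score_questionnaire(r)$total, 10 * 3 * 3)
  ## missing subcategory with reported exposure is an error
  r$freq_cat[r$category == "supplements"] <- NA
  expect_error(score_questionnaire(r), "required")
})

test_that("scenario resolution applies precedence and imputation rules", {
  defaults <- reconstruction_defaults()
  ## all-no, no self-report: every scenario inert
  sc <- resolve_scenarios(flat_response("no"), NULL, defaults)
  expect_true(all(sc$source == "none"))
  ## a self-report zeroes the questionnaire scenario of its category
  rep1 <- data.frame(category = "supplements", product = "x", amount = 2,
                     freq_per_week = 7, duration_days = 300,
                     simultaneous = TRUE)
  sc <- resolve_scenarios(flat_response("yes", "ge6", "gt2y"), rep1, defaults)
  expect_equal(sc$source[sc$category == "supplements"], "self_report")
  expect_equal(sum(sc$source == "questionnaire"), 4)
  ## missing amount imputed with the cohort mean of reported values
  defaults$cohort_means <- list(amount = c(supplements = 5),
                                freq_per_week = c(supplements = 7))
  rep2 <- rep1; rep2$amount <- NA
  sc <- resolve_scenarios(flat_response("no"), rep2, defaults)
  expect_equal(sc$amount_mean[sc$source == "self_report"], 5)
  ## frequency and duration midpoints for questionnaire scenarios
  sc <- resolve_scenarios(flat_response("unsure", "3to5", "6to12m"), NULL,
                          reconstruction_defaults())
  expect_equal(unique(sc$ef_per_day), 4 / 7)
  expect_equal(unique(sc$ed_days), 9 * 365.25 / 12)
  expect_error(resolve_scenarios(flat_response("no"),
                                 data.frame(category = "candy", product = "z",
                                            amount = 1, freq_per_week = 1,
                                            duration_days = 10,
                                            simultaneous = TRUE)),
               "unknown category")
})

test_that("averaging time follows the max/sum rules", {
  sc <- data.frame(category = food_categories(),
                   source = "questionnaire", belief = "yes",
                   amount_mean = 1, amount_sd = 0, ef_per_day = 1,
                   ed_days = c(90, 270, 0, 0, 0), simultaneous = TRUE)
  expect_equal(compute_averaging_time(sc, "questionnaire"), 270)
  ## discontinuous self-report periods are summed
  sf <- data.frame(category = c("supplements", "supplements"),
                   source = "self_report", belief = "yes",
                   amount_mean = 1, amount_sd = 0, ef_per_day = 1,
                   ed_days = c(100, 200), simultaneous = FALSE)
  expect_equal(compute_averaging_time(sf, "self_report"), 300)
  ## simultaneous consumption contributes through the maximum
  sf$simultaneous <- TRUE
  expect_equal(compute_averaging_time(sf, "self_report"), 200)
  sf$ed_days[1] <- -5
  expect_error(compute_averaging_time(sf, "self_report"), "negative")
})

test_that("growth adjustment reproduces the published worked example", {
  ref <- generate_growth_reference()
  boy <- list(age = 5, sex = "male", weight_kg = 20,
              lag_days = 1.5 * 365.25)
  g <- growth_adjusted_weight(boy, ref, n_draws = 1, cv = 0)
  expect_equal(g$gamma, 18.3 / 15.3)        # ~1.2
  expect_equal(round(g$bw_b, 1), 16.7)
  ## adults and zero lag are unadjusted
  adult <- list(age = 40, sex = "female", weight_kg = 55, lag_days = 500)
  expect_equal(growth_adjusted_weight(adult, ref, 1, cv = 0)$bw_b, 55)
  boy0 <- boy; boy0$lag_days <- 0
  expect_equal(growth_adjusted_weight(boy0, ref, 1, cv = 0)$bw_b, 20)
  ## stochastic draws are truncated and centred near the point GRC
  d <- growth_adjusted_weight(boy, ref, n_draws = 5000, cv = 0.16,
                              seed = 1)
  expect_true(all(20 / d$bw_b >= 0.5))
  expect_equal(mean(20 / d$bw_b), g$gamma, tolerance = 0.02)
})

test_that("the intake equation matches the hand-computed oracle", {
  sc <- data.frame(y = 2, amount = 350, ef_per_day = 1, ed_days = 180)
  expect_equal(avdi_intake(sc, bw_b = 16.7, at = 180), 2 * 350 / 16.7)
  ## doubling body weight halves the result
  expect_equal(avdi_intake(sc, bw_b = 2 * 16.7, at = 180),
               avdi_intake(sc, bw_b = 16.7, at = 180) / 2)
  expect_equal(avdi_intake(data.frame(y = 0, amount = 350, ef_per_day = 1,
                                      ed_days = 180), 16.7, 180), 0)
  expect_error(avdi_intake(sc, bw_b = 0, at = 180), "BW_b")
  expect_error(avdi_intake(sc, bw_b = 16.7, at = 0), "AT")
})

test_that("a point-mass posterior makes reconstruction exactly deterministic", {
  fit <- point_mass_fit(y0 = 10)
  ref <- generate_growth_reference()
  refs <- list(growth = ref, creatinine = creatinine_reference(),
               pk = pk_constants())
  defaults <- reconstruction_defaults(grc_cv = 0, jam_sd_g = 0)
  boy <- list(participant_id = "P1", age = 5, sex = "male", weight_kg = 20,
              height_cm = 110, lag_days = 1.5 * 365.25)
  resp <- flat_response("no")
  resp[resp$category == "sport_drinks",
       c("exposed", "freq_cat", "dur_cat")] <- list("yes", "ge6", "6to12m")
  urine <- list(mehp_ugL = 0, mehhp_ugL = 0, meohp_ugL = 0,
                creatinine_gL = 1)
  d <- reconstruct_participant(boy, resp, NULL, urine, fit, refs = refs,
                               defaults = defaults, n_draws = 50, seed = 1)
  ## hand oracle: Y = 10 ppm, M = 350 ml, EF = 1/day, ED = AT -> ED/AT = 1,
  ## BW_b = 20 / (18.3/15.3)
  bw_b <- 20 / (18.3 / 15.3)
  expected <- 10 * 350 * 1 / bw_b
  expect_equal(unique(d$draws$avdi_qn), expected)
  expect_equal(unique(d$draws$avdi_env), 0)
  expect_equal(d$draws$avdi_all, d$draws$avdi_qn + d$draws$avdi_sf +
                 d$draws$avdi_env)
  ## windowed variant divides by the longer averaging time and present BW
  at <- 9 * 365.25 / 12
  expected_w <- 10 * 350 * 1 * at / ((at + boy$lag_days) * 20)
  expect_equal(unique(d$draws$avdi_qn_w), expected_w)
})

test_that("participants without urine are flagged ineligible", {
  fit <- point_mass_fit()
  d <- reconstruct_participant(
    list(participant_id = "P9", age = 30, sex = "male", weight_kg = 70,
         height_cm = 175, lag_days = 400),
    flat_response("no"), NULL, NULL, fit, n_draws = 10)
  expect_false(d$eligible)
  expect_null(d$draws)
})

test_that("no exposure and zero metabolites give identically zero draws", {
  fit <- point_mass_fit()
  urine <- list(mehp_ugL = 0, mehhp_ugL = 0, meohp_ugL = 0,
                creatinine_gL = 1)
  d <- reconstruct_participant(
    list(participant_id = "P2", age = 30, sex = "female", weight_kg = 60,
         height_cm = 165, lag_days = 450),
    flat_response("no"), NULL, urine, fit, n_draws = 20, seed = 3)
  expect_true(all(as.matrix(d$draws[, c("avdi_qn", "avdi_sf", "avdi_env",
                                        "avdi_all")]) == 0))
})
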
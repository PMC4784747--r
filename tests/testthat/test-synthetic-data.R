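test_that("configuration validation rejects invalid inputs", {
  expect_error(synth_config(true_p_d = c(0.1, 0.1, 0.1, 0.1, 1.2)),
               "probability")
  expect_error(synth_config(censor_fraction = -0.1), "probability")
  expect_error(synth_config(bin_edges = c(2, 10, 100)), "first edge")
  expect_error(synth_config(bin_edges = c(1, 100, 10)), "increasing")
  expect_error(synth_config(n_children = -3), "non-negative")
  expect_error(synth_config(n_children = 0, n_adolescents = 0, n_adults = 0,
                            n_missing_urine = c(0, 0, 0),
                            n_negligible = c(0, 0, 0)) |>
                 generate_cohort(seed = 1), "empty cohort")
})

test_that("survey generation honours degenerate probabilities", {
  cfg <- single_category_config(n_per_agency = 50, p_d = 1, beta = 0)
  cfg$censor_fraction <- 0
  sv <- generate_concentration_survey(cfg, seed = 1)
  expect_true(all(sv$status == "detected_quantified"))
  expect_true(all(sv$value_ppm >= 1))
})

test_that("detection counts follow the binomial law", {
  ## one stratum of n = 1166 with detection probability 0.105
  np <- matrix(0, 5, 2, dimnames = list(food_categories(), agencies()))
  np["supplements", "KBOH"] <- 1166
  cfg <- synth_config(n_products = np,
                      true_p_d = c(0.1, 0.1, 0.1, 0.1, 0.105),
                      n_children = 1, n_adolescents = 0, n_adults = 0,
                      n_missing_urine = c(0, 0, 0), n_negligible = c(0, 0, 0))
  sv <- generate_concentration_survey(cfg, seed = 5)
  n_det <- sum(sv$status != "not_detected")
  expected <- 1166 * 0.105
  sd3 <- 3 * sqrt(1166 * 0.105 * 0.895)
  expect_gt(n_det, expected - sd3)
  expect_lt(n_det, expected + sd3)
})

test_that("identical seeds reproduce identical outputs, different seeds differ", {
  cfg <- small_cohort_config()
  expect_identical(generate_concentration_survey(cfg, seed = 3),
                   generate_concentration_survey(cfg, seed = 3))
  expect_false(identical(generate_concentration_survey(cfg, seed = 3),
                         generate_concentration_survey(cfg, seed = 4)))
  expect_identical(generate_cohort(cfg, seed = 3),
                   generate_cohort(cfg, seed = 3))
  expect_false(identical(generate_cohort(cfg, seed = 3)$participants,
                         generate_cohort(cfg, seed = 4)$participants))
})

test_that("cohort structure matches the configured sizes and cut-offs", {
  coh <- generate_cohort(small_cohort_config(), seed = 9)
  p <- coh$participants
  expect_equal(nrow(p), 45)
  expect_true(all(p$age[p$age_group == "children"] < 12))
  expect_true(all(p$age[p$age_group == "adolescents"] >= 12 &
                    p$age[p$age_group == "adolescents"] < 18))
  expect_true(all(p$age[p$age_group == "adults"] >= 18))
  expect_equal(sum(!p$has_urine), 3)
  expect_equal(sum(p$negligible_freq), 1)
  ## every participant has a complete 5-category questionnaire
  expect_equal(nrow(coh$questionnaires), 45 * 5)
  ## urine only for participants with a sample, with valid LOD flags
  expect_equal(nrow(coh$urine), sum(p$has_urine))
  expect_true(all(coh$urine$creatinine_gL > 0))
})

test_that("all-no questionnaires give zero true dietary intake", {
  pe <- matrix(c(0, 0, 1), 5, 3, byrow = TRUE)
  cfg <- small_cohort_config(p_exposed = pe, p_self_report = c(0, 0, 0))
  coh <- generate_cohort(cfg, seed = 2)
  expect_true(all(coh$questionnaires$exposed == "no"))
  expect_true(all(coh$ground_truth$avdi_qn == 0))
  expect_true(all(coh$ground_truth$avdi_sf == 0))
})

test_that("ground truth is additive, non-negative and finite", {
  coh <- generate_cohort(small_cohort_config(), seed = 21)
  gt <- coh$ground_truth
  ok <- !is.na(gt$avdi_env)
  expect_equal(gt$avdi_all[ok],
               gt$avdi_qn[ok] + gt$avdi_sf[ok] + gt$avdi_env[ok])
  expect_true(all(gt$avdi_qn >= 0 & is.finite(gt$avdi_qn)))
  expect_true(all(gt$avdi_sf >= 0 & is.finite(gt$avdi_sf)))
  expect_true(all(gt$avdi_env[ok] >= 0 & is.finite(gt$avdi_env[ok])))
})

test_that("growth reference holds the anchor medians and is monotone", {
  ref <- generate_growth_reference()
  expect_equal(lookup_median_weight(ref, "male", 5), 18.3)
  expect_equal(lookup_median_weight(ref, "male", 3.5), 15.3)
  for (sex in c("male", "female")) {
    w <- lookup_median_weight(ref, sex, seq(0, 18, by = 0.5))
    expect_true(all(diff(w) >= 0))
  }
})
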
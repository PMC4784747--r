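test_that("posterior draws satisfy the probability and ordering invariants", {
  cfg <- single_category_config(n_per_agency = 300)
  sv <- generate_concentration_survey(cfg, seed = 8)
  fit <- suppressWarnings(fit_concentration_model(
    sv, mcmc = mcmc_config(2, 400, 800, seed = 9)))
  d <- fit$categories$supplements$draws
  expect_equal(d$p_d + d$p_0 + d$p_1, rep(1, nrow(d)), tolerance = 1e-12)
  wsum <- d$w1 + d$w2 + d$w3
  expect_equal(wsum, rep(1, nrow(d)), tolerance = 1e-12)
  expect_true(all(d$e_y >= 1))
  expect_true(all(d$e_c <= d$e_y + 1e-12))
  expect_true(all(d$p_d >= 0 & d$p_d <= 1))
})

test_that("degenerate single-bin posterior recovers the closed-form means", {
  ## sigma -> 0, mu = log(10), p_D = 0.5, p_1 = 0: E(Y) = 10, E(C) = 5
  post <- category_posterior(p_d = 0.5, w = 1, mu = log(10), sigma = 0,
                             p_1 = 0)
  ec <- expected_concentrations(post)
  expect_equal(unname(ec$e_y[["mean"]]), 10)
  expect_equal(unname(ec$e_c[["mean"]]), 5)
  ## p_D = 0, p_1 = 0 gives E(C) = 0
  post0 <- category_posterior(p_d = 0, w = 1, mu = log(10), sigma = 0,
                              p_1 = 0)
  expect_equal(unname(expected_concentrations(post0)$e_c[["mean"]]), 0)
  expect_error(expected_concentrations(structure(
    list(draws = data.frame()), class = "category_posterior")), "empty")
})

test_that("the E(C) composition reproduces published category values", {
  est <- published_category_estimates()
  tea <- est[est$category == "tea_drinks", ]
  expect_equal(round(ec_composition(tea$p_d, tea$e_y, tea$p_1), 1), 0.8)
  jam <- est[est$category == "fruit_jam", ]
  expect_equal(round(ec_composition(jam$p_d, jam$e_y, jam$p_1), 1), 5.1)
})

test_that("MCMC detection posterior matches a brute-force grid oracle", {
  ## tiny two-stratum survey small enough for 2-d numeric integration
  rec <- make_records(c(rep("KBOH", 15), rep("TFDA", 20)), "tea_drinks",
                      c(rep("detected_quantified", 3), rep("not_detected", 12),
                        rep("detected_quantified", 2),
                        rep("not_detected", 18)))
  rec$value_ppm[rec$status == "detected_quantified"] <- c(2, 5, 20, 3, 50)
  det <- c(3, 2); tot <- c(15, 20)
  g <- seq(-12, 12, by = 0.02)
  ll <- function(a, b) {
    e1 <- a; e2 <- a + b
    (tot[1] - det[1]) * plogis(e1, log.p = TRUE) +
      det[1] * plogis(-e1, log.p = TRUE) +
      (tot[2] - det[2]) * plogis(e2, log.p = TRUE) +
      det[2] * plogis(-e2, log.p = TRUE)
  }
  L <- outer(g, g, function(a, b) {
    ll(a, b) + dnorm(a, 0, 10, log = TRUE) + dnorm(b, 0, 10, log = TRUE)
  })
  W <- exp(L - max(L))
  oracle <- sum(rowSums(W) * (1 - plogis(g))) / sum(W)
  fit <- suppressWarnings(fit_concentration_model(
    rec, mcmc = mcmc_config(4, 1500, 8000, seed = 42)))
  expect_equal(mean(fit$categories$tea_drinks$draws$p_d), oracle,
               tolerance = 0.01)
})

test_that("posterior-mean detection probability is nearly unbiased at n = 2000", {
  cfg <- single_category_config(n_per_agency = 1000, p_d = 0.2)
  sv <- generate_concentration_survey(cfg, seed = 31)
  fit <- suppressWarnings(fit_concentration_model(
    sv, mcmc = mcmc_config(2, 800, 1600, seed = 32)))
  expect_lt(abs(mean(fit$categories$supplements$draws$p_d) - 0.2), 0.02)
})

test_that("concentration sampling respects the belief levels", {
  est <- published_category_estimates()
  sup <- est[est$category == "supplements", ]
  ## point posterior built from the published supplements summaries
  post <- category_posterior(p_d = sup$p_d, w = 1, mu = log(sup$e_y),
                             sigma = 0, p_1 = sup$p_1)
  expect_equal(sample_concentration(post, "no", 100, seed = 1), numeric(100))
  expect_error(sample_concentration(post, "maybe", 10), "belief")
  y_yes <- sample_concentration(post, "yes", 1e4, seed = 2)
  expect_equal(mean(y_yes), sup$e_y)  # degenerate mixture: constant
  y_uns <- sample_concentration(post, "unsure", 1e5, seed = 3)
  ec <- unname(expected_concentrations(post)$e_c[["mean"]])
  ## sample mean matches the analytic E(C) within Monte Carlo error, and
  ## the published rounded value within printing precision
  se <- sd(y_uns) / sqrt(length(y_uns))
  expect_lt(abs(mean(y_uns) - ec), 4 * se)
  expect_lt(abs(mean(y_uns) - sup$e_c), 0.2)
  expect_gte(mean(y_yes), mean(y_uns))
})

test_that("fitting is reproducible and flags prior-only categories", {
  rec <- make_records(c("KBOH", "KBOH", "TFDA"), "sport_drinks",
                      c("detected_censored", "not_detected",
                        "not_detected"))
  w <- capture_warnings(fit_concentration_model(
    rec, mcmc = mcmc_config(1, 100, 200, seed = 4)))
  expect_true(any(grepl("fall back to priors", w)))
  cfg <- single_category_config(n_per_agency = 100)
  sv <- generate_concentration_survey(cfg, seed = 12)
  f1 <- suppressWarnings(fit_concentration_model(
    sv, mcmc = mcmc_config(1, 200, 400, seed = 5)))
  f2 <- suppressWarnings(fit_concentration_model(
    sv, mcmc = mcmc_config(1, 200, 400, seed = 5)))
  expect_identical(f1$categories$supplements$draws,
                   f2$categories$supplements$draws)
  expect_error(fit_concentration_model(sv[0, ]), "no records")
})
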
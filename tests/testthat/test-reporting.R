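test_that("exposure classification uses left-closed thresholds", {
  x <- classify_exposure(c(0, 19.999, 20, 49.9, 50, 99.9, 100, 414.1))
  expect_equal(as.character(x),
               c("low", "low", "medium", "medium", "high", "high",
                 "very_high", "very_high"))
  expect_error(classify_exposure(-1), "non-negative")
  expect_error(exposure_scheme(c(50, 20, 100)), "increasing")
})

test_that("exposure tables conserve counts and round percentages", {
  df <- data.frame(
    age_group = "children",
    group = factor(rep(c("low", "medium", "high", "very_high"),
                       times = c(85, 83, 34, 25)),
                   levels = c("low", "medium", "high", "very_high")))
  tab <- exposure_table(df)
  expect_equal(tab$n, 227)
  expect_equal(c(tab$low, tab$medium, tab$high, tab$very_high),
               c(85, 83, 34, 25))
  expect_equal(c(tab$low_pct, tab$medium_pct, tab$high_pct,
                 tab$very_high_pct), c(37, 37, 15, 11))
  ## percentages sum to 100 within rounding slack
  expect_lte(abs(tab$low_pct + tab$medium_pct + tab$high_pct +
                   tab$very_high_pct - 100), 2)
  ## a single participant is 100% of its cell
  one <- data.frame(age_group = "adults", group = classify_exposure(30))
  t1 <- exposure_table(one)
  expect_equal(t1$medium, 1)
  expect_equal(t1$medium_pct, 100)
  expect_equal(t1$n, 1)
})

test_that("chi-square test equals the brute-force expected-count oracle", {
  chisq_oracle <- function(m) {
    e <- outer(rowSums(m), colSums(m)) / sum(m)
    sum((m - e)^2 / e)
  }
  m1 <- rbind(c(10, 0), c(0, 10))
  r1 <- compare_groups_chisq(m1)
  expect_equal(r1$statistic, 20)             # no continuity correction
  expect_equal(r1$statistic, chisq_oracle(m1))
  m2 <- rbind(children = c(85, 83, 34, 25), adults = c(82, 9, 3, 1))
  r2 <- compare_groups_chisq(m2)
  expect_equal(r2$statistic, chisq_oracle(m2))
  expect_equal(r2$df, 3)
  expect_lt(r2$p_value, 1e-4)
  ## identical rows carry no signal
  r3 <- compare_groups_chisq(rbind(c(5, 7, 3), c(5, 7, 3)))
  expect_equal(r3$statistic, 0)
  expect_equal(r3$p_value, 1)
  expect_error(compare_groups_chisq(matrix(0, 2, 4)), "positive counts")
  ## all-zero columns are dropped before testing
  r4 <- compare_groups_chisq(cbind(m1, c(0, 0)))
  expect_equal(r4$statistic, 20)
})

test_that("component correlations behave at the degenerate extremes", {
  x <- c(1, 2, 3, 4, 5)
  df <- data.frame(age_group = "children", avdi_env = x, avdi_qn = x,
                   avdi_sf = -x)
  cc <- component_correlations(df)
  expect_equal(cc$cor[cc$component == "avdi_qn"], 1)
  expect_equal(cc$cor[cc$component == "avdi_sf"], -1)
  ## constant components are flagged as undefined
  df$avdi_qn <- 1
  cc <- component_correlations(df)
  expect_true(is.na(cc$cor[cc$component == "avdi_qn"]))
})

test_that("independent components show no spurious correlation", {
  ## null-simulation: independent components, n = 200, 20 seeds
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    df <- data.frame(age_group = "children", avdi_env = rlnorm(200),
                     avdi_qn = rlnorm(200), avdi_sf = rlnorm(200))
    all(abs(component_correlations(df)$cor) < 0.2)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("posterior summaries use interpolated quantiles", {
  d <- data.frame(avdi_all = rep(4.2, 100))
  s <- summarize_posterior(d)
  expect_equal(s$mean, 4.2)
  expect_equal(s$median, 4.2)
  expect_equal(s$q2.5, 4.2)
  expect_equal(s$q97.5, 4.2)
  s2 <- summarize_posterior(data.frame(x = 1:10000))
  expect_equal(s2$mean, 5000.5)
  expect_equal(s2$median, 5000.5)
  expect_error(summarize_posterior(data.frame()), "empty")
})
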
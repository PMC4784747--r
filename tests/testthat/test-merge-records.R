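test_that("repeated quantified measurements collapse to their geometric mean", {
  r <- make_records("TFDA", "tea_drinks", "detected_quantified",
                    value = c(10, 1000), product_id = "prod1")
  m <- merge_product_records(r)
  expect_equal(nrow(m), 1)
  expect_equal(m$value_ppm, sqrt(10 * 1000))  # 100
})

test_that("a quantified measurement dominates a censored one", {
  r <- make_records("KBOH", "supplements",
                    c("detected_quantified", "detected_censored"),
                    value = c(50, NA), product_id = "prod2")
  m <- merge_product_records(r)
  expect_equal(m$status, "detected_quantified")
  expect_equal(m$value_ppm, 50)
})

test_that("single records pass through unchanged and counts never grow", {
  r <- make_records(c("KBOH", "TFDA", "KBOH"), "fruit_jam",
                    c("not_detected", "detected_censored",
                      "detected_quantified"),
                    value = c(NA, NA, 7))
  m <- merge_product_records(r)
  expect_equal(nrow(m), 3)
  expect_setequal(m$product_id, r$product_id)
  expect_equal(sort(m$value_ppm, na.last = TRUE), c(7, NA, NA))
  ## same product id under different agencies stays separate
  r2 <- make_records(c("KBOH", "TFDA"), "fruit_jam", "detected_quantified",
                     value = c(3, 9), product_id = "shared")
  expect_equal(nrow(merge_product_records(r2)), 2)
})

test_that("conflicting categories for one product raise an error", {
  r <- make_records("KBOH", c("tea_drinks", "fruit_jam"),
                    "detected_quantified", value = c(2, 3),
                    product_id = "prodX")
  expect_error(merge_product_records(r), "conflicting categories")
})
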
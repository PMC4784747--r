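urine0 <- function(mehp = 0, mehhp = 0, meohp = 0, cr = 1) {
  list(mehp_ugL = mehp, mehhp_ugL = mehhp, meohp_ugL = meohp,
       creatinine_gL = cr)
}

test_that("molar excretion sum follows the hand unit-conversion oracle", {
  expect_equal(molar_ue_sum(urine0()), 0)
  ## 27.834 ug/L of MEHP (MW 278.34) in 1 g/L creatinine = 0.1 umol/g
  expect_equal(molar_ue_sum(urine0(mehp = 27.834)), 0.1)
  ## linearity: doubling all metabolites doubles UE_sum
  s1 <- urine0(5, 12, 8); s2 <- urine0(10, 24, 16)
  expect_equal(molar_ue_sum(s2), 2 * molar_ue_sum(s1))
  ## halving creatinine doubles UE_sum
  expect_equal(molar_ue_sum(urine0(5, 12, 8, cr = 0.5)),
               2 * molar_ue_sum(s1))
  expect_error(molar_ue_sum(urine0(cr = 0)), "creatinine")
  expect_error(molar_ue_sum(urine0(mehp = -1)), ">= 0")
})

test_that("below-LOD values are substituted by LOD/sqrt(2)", {
  s <- urine0(mehp = 0.7)
  s$mehp_below_lod <- TRUE
  expect_equal(molar_ue_sum(s), (0.7 / sqrt(2)) / 278.34)
  ## policy is configurable
  expect_equal(molar_ue_sum(s, lod_factor = 0.5), 0.35 / 278.34)
})

test_that("adult back-calculation matches the hand-computed oracle", {
  ## UE_sum = 0.1 umol/g, CE = 23 mg/kg/day, F_UE = 0.32, MW = 390.56
  male <- list(age = 40, sex = "male", weight_kg = 70)
  female <- list(age = 40, sex = "female", weight_kg = 60)
  s <- urine0(mehp = 27.834)
  expect_equal(avdi_env(s, male), 0.1 * 23 / (0.32 * 1000) * 390.56)
  expect_equal(round(avdi_env(s, male), 2), 2.81)
  ## the female/male ratio is forced to 18/23
  expect_equal(avdi_env(s, female) / avdi_env(s, male), 18 / 23)
  ## zero excretion gives zero intake
  expect_equal(avdi_env(urine0(), male), 0)
})

test_that("child back-calculation scales inversely with body weight", {
  s <- urine0(mehp = 27.834)
  c1 <- list(age = 6, sex = "male", weight_kg = 20, height_cm = 115)
  c2 <- list(age = 6, sex = "male", weight_kg = 40, height_cm = 115)
  expect_equal(avdi_env(s, c1), 2 * avdi_env(s, c2))
  ## inverse proportionality to F_UE
  pk2 <- pk_constants(f_ue = 0.16)
  expect_equal(avdi_env(s, c1, pk = pk2), 2 * avdi_env(s, c1))
  ## child CE table is monotone in height, so taller children at equal
  ## weight get larger intakes
  c3 <- list(age = 10, sex = "male", weight_kg = 20, height_cm = 145)
  expect_gt(avdi_env(s, c3), avdi_env(s, c1))
})

test_that("back-calculation validates its inputs", {
  s <- urine0(mehp = 5)
  expect_error(avdi_env(s, list(age = 6, sex = "other", weight_kg = 20,
                                height_cm = 110)), "sex")
  expect_error(avdi_env(s, list(age = 6, sex = "male", weight_kg = 20,
                                height_cm = NA)), "height")
  expect_error(avdi_env(s, list(age = 6, sex = "male", weight_kg = 0,
                                height_cm = 110)), "weight")
})
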
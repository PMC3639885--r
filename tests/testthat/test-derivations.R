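test_that("BMI derivation matches the hand oracle and is unit-invariant", {
  rec <- derive_bmi(make_record(height = 1.8288, mass = 78.1818))
  bmi <- get_quantity(rec, "BodyMassIndex")
  expect_equal(bmi$value, 78.1818 / 1.8288^2, tolerance = 1e-12)
  expect_equal(bmi$value, 23.3762, tolerance = 1e-4)
  expect_identical(bmi$unit, "kilogram-per-meter-squared")

  # unit height: BMI equals mass numerically
  rec1 <- derive_bmi(make_record(height = 1, mass = 63.7))
  expect_equal(get_quantity(rec1, "BodyMassIndex")$value, 63.7)

  # height given in centimeters gives the same BMI
  rec_cm <- patient_record("cm")
  rec_cm <- set_attribute(rec_cm, "Height", quantity(182.88, "centimeter"))
  rec_cm <- set_attribute(rec_cm, "Mass", quantity(78.1818, "kilogram"))
  expect_equal(get_quantity(derive_bmi(rec_cm), "BodyMassIndex")$value,
               bmi$value, tolerance = 1e-12)

  expect_error(derive_bmi(make_record(mass = 70)), "Height")
  expect_error(derive_bmi(make_record(height = 0, mass = 70)),
               "non-positive")
})

test_that("Friedewald LDL selects k from the unit system", {
  # mg/dl working system: k = 0.20
  rec <- derive_ldl(make_record(chol = 227, hdl = 55, tg = 84))
  ldl <- get_quantity(rec, "SerumLDLCholesterolConcentration")
  expect_equal(ldl$value, 227 - 55 - 0.2 * 84)  # 155.2
  expect_identical(ldl$unit, "milligram-per-deciliter")

  # degenerate: C = H, T = 0 gives LDL 0
  rec0 <- derive_ldl(make_record(chol = 180, hdl = 180, tg = 0))
  expect_equal(get_quantity(rec0, "SerumLDLCholesterolConcentration")$value,
               0)

  # same panel expressed in mmol/L uses k = 0.45 and agrees after
  # conversion to 1e-6 relative
  mm <- make_record(chol = 227 / 38.67, hdl = 55 / 38.67, tg = 84 / 88.57,
                    conc_unit = "milli-mole-per-liter")
  ldl_mm <- get_quantity(derive_ldl(mm), "SerumLDLCholesterolConcentration")
  expect_identical(ldl_mm$unit, "milli-mole-per-liter")
  ldl_mgdl_conv <- convert_quantity(quantity(155.2, "mg/dl"), "mmol/L",
                                    analyte = "ldl")$value
  # k = 0.45 is the rounded clinical constant (0.20 * 88.57/38.67 = 0.458),
  # so agreement is to the constant's own precision, not machine precision
  expect_equal(ldl_mm$value, ldl_mgdl_conv, tolerance = 5e-3)

  expect_error(derive_ldl(make_record(chol = 200, hdl = 50)), "HDL")
  expect_error(derive_ldl(make_record(chol = 100, hdl = 90, tg = 200)),
               "implausible")
  expect_error(derive_ldl(make_record(chol = 300, hdl = 50, tg = 450),
                          tg_guard = TRUE), "400")
  # guard defaults off
  expect_silent(derive_ldl(make_record(chol = 300, hdl = 50, tg = 450)))
})

test_that("Framingham per-factor points match every printed band edge", {
  pts <- function(age = 40, hdl = 46, chol = 150, sbp = 125,
                  treated = FALSE, smoker = FALSE, diabetic = FALSE) {
    framingham_points(framingham_profile(
      age, chol, hdl, sbp, bp_treated = treated, smoker = smoker,
      diabetic = diabetic))$per_factor_points
  }
  age_expect <- c(`30` = 0, `34` = 0, `35` = 2, `39` = 2, `40` = 5,
                  `44` = 5, `45` = 6, `49` = 6, `50` = 8, `54` = 8,
                  `55` = 10, `59` = 10, `60` = 11, `64` = 11, `65` = 12,
                  `69` = 12, `70` = 14, `74` = 14, `75` = 15, `90` = 15)
  for (a in names(age_expect)) {
    expect_equal(pts(age = as.numeric(a))[["age"]], age_expect[[a]],
                 info = paste("age", a))
  }
  hdl_expect <- c(`20` = 2, `34` = 2, `35` = 1, `44` = 1, `45` = 0,
                  `49` = 0, `50` = -1, `59` = -1, `60` = -2, `62` = -2)
  for (h in names(hdl_expect)) {
    expect_equal(pts(hdl = as.numeric(h))[["hdl"]], hdl_expect[[h]],
                 info = paste("hdl", h))
  }
  chol_expect <- c(`100` = 0, `159` = 0, `160` = 1, `199` = 1, `200` = 2,
                   `239` = 2, `240` = 3, `279` = 3, `280` = 4, `400` = 4)
  for (ch in names(chol_expect)) {
    expect_equal(pts(chol = as.numeric(ch))[["total_cholesterol"]],
                 chol_expect[[ch]], info = paste("chol", ch))
  }
  sbp_unt <- c(`100` = -2, `119` = -2, `120` = 0, `129` = 0, `130` = 1,
               `139` = 1, `140` = 2, `159` = 2, `160` = 3, `220` = 3)
  sbp_trt <- c(`100` = 0, `119` = 0, `120` = 2, `129` = 2, `130` = 3,
               `139` = 3, `140` = 4, `159` = 4, `160` = 5, `220` = 5)
  for (s in names(sbp_unt)) {
    expect_equal(pts(sbp = as.numeric(s))[["sbp"]], sbp_unt[[s]],
                 info = paste("sbp untreated", s))
    expect_equal(pts(sbp = as.numeric(s), treated = TRUE)[["sbp"]],
                 sbp_trt[[s]], info = paste("sbp treated", s))
  }
  expect_equal(pts(smoker = TRUE)[["smoker"]], 4)
  expect_equal(pts(diabetic = TRUE)[["diabetic"]], 3)
  expect_equal(pts()[["smoker"]], 0)
  expect_equal(pts()[["diabetic"]], 0)

  # hand-summed totals
  low <- framingham_points(framingham_profile(30, 150, 46, 118))
  expect_identical(low$total_points, -2L)
  expect_identical(low$category, "low")
  t2 <- framingham_points(framingham_profile(77, 227, 55, 128))
  expect_identical(t2$total_points, 16L)

  expect_error(framingham_profile(29, 200, 50, 120), "below 30")
  expect_error(framingham_profile(40, 200, 50, 120, sex = "female"),
               "men's")
})

test_that("Framingham points are monotone in each factor", {
  base <- list(age = 50, chol = 200, hdl = 50, sbp = 130)
  total <- function(age = base$age, chol = base$chol, hdl = base$hdl,
                    sbp = base$sbp) {
    framingham_points(framingham_profile(age, chol, hdl, sbp))$total_points
  }
  grid <- seq(30, 85, by = 2.5)
  expect_true(all(diff(vapply(grid, function(a) total(age = a),
                              integer(1))) >= 0))
  grid <- seq(100, 350, by = 10)
  expect_true(all(diff(vapply(grid, function(c_) total(chol = c_),
                              integer(1))) >= 0))
  grid <- seq(90, 200, by = 5)
  expect_true(all(diff(vapply(grid, function(s) total(sbp = s),
                              integer(1))) >= 0))
  grid <- seq(20, 80, by = 2.5)
  expect_true(all(diff(vapply(grid, function(h) total(hdl = h),
                              integer(1))) <= 0))
})

test_that("points-to-risk lookup and ternary quantization agree with the tables", {
  expect_equal(framingham_percent(20),
               list(percent = 11, comparator = "="))
  expect_equal(framingham_percent(25),
               list(percent = 30, comparator = ">="))
  expect_equal(framingham_percent(40),
               list(percent = 30, comparator = ">="))
  expect_equal(framingham_percent(0),
               list(percent = 1, comparator = "<"))
  full <- c(`9` = 1, `10` = 1, `11` = 1, `12` = 1, `13` = 2, `14` = 2,
            `15` = 3, `16` = 4, `17` = 5, `18` = 6, `19` = 8, `20` = 11,
            `21` = 14, `22` = 17, `23` = 22, `24` = 27)
  for (p in names(full)) {
    expect_equal(framingham_percent(as.integer(p))$percent, full[[p]],
                 info = p)
  }
  expect_identical(framingham_category(15), "medium")
  expect_identical(framingham_category(9), "low")
  expect_identical(framingham_category(10), "medium")
  expect_identical(framingham_category(19), "medium")
  expect_identical(framingham_category(20), "high")
  expect_identical(framingham_category(-2), "low")

  # risk percent is non-decreasing in points, so the category boundaries
  # respect the risk ordering
  pcts <- vapply(-2:30, function(p) framingham_percent(p)$percent,
                 numeric(1))
  expect_true(all(diff(pcts) >= 0))
})

test_that("record-level Framingham derivation enforces its contract", {
  rec <- make_record(age = 77, chol = 227, hdl = 55, sbp = 128,
                     sex = "male", smoker = FALSE, diabetic = FALSE)
  out <- derive_framingham(rec)
  expect_identical(out$result$total_points, 16L)
  expect_equal(get_quantity(out$record,
                            "GeneralCVDFraminghamRiskScore")$value, 16)
  # status must be explicit, never assumed
  expect_error(derive_framingham(make_record(age = 77, chol = 227,
                                             hdl = 55, sbp = 128,
                                             sex = "male")),
               "smoking and diabetes")
  expect_error(derive_framingham(make_record(age = 77, chol = 227,
                                             hdl = 55, sbp = 128,
                                             sex = "female",
                                             smoker = FALSE,
                                             diabetic = FALSE)),
               "male")
})
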
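test_that("builtin model registries carry the published thresholds", {
  aha <- builtin_models("aha")
  mod <- builtin_models("modified")
  at_risk_bound <- function(m) {
    bs <- Filter(function(b) b$at_risk == 1, m$bands)
    if (is.finite(bs[[1]]$lower)) bs[[1]]$lower else bs[[1]]$upper
  }
  expect_equal(at_risk_bound(aha$sbp), 140)
  expect_equal(at_risk_bound(aha$dbp), 90)
  expect_equal(at_risk_bound(aha$chol), 5.0)
  expect_equal(at_risk_bound(aha$hdl), 1.03)
  expect_equal(at_risk_bound(aha$tg), 2.26)
  expect_equal(at_risk_bound(aha$bmi), 25)
  expect_equal(at_risk_bound(aha$ldl), 160)
  expect_equal(at_risk_bound(mod$chol), 5.2)
  expect_equal(at_risk_bound(mod$hdl), 0.89)
  expect_equal(at_risk_bound(mod$tg), 2.63)
  expect_equal(at_risk_bound(mod$bmi), 26)
  expect_equal(at_risk_bound(mod$sbp), 140)
  expect_equal(at_risk_bound(mod$ldl), 160)
  # at-risk side inclusive: HDL <= 0.89 flagged, BMI >= 26 flagged
  hdl_band <- Filter(function(b) b$at_risk == 1, mod$hdl$bands)[[1]]
  expect_true(hdl_band$upper_inclusive)
  bmi_band <- Filter(function(b) b$at_risk == 1, mod$bmi$bands)[[1]]
  expect_true(bmi_band$lower_inclusive)
})

test_that("binary classification converts, matches and reports gaps", {
  mod <- builtin_models("modified")
  t2 <- table2_record()
  cls <- classify_binary(t2, mod$chol)
  expect_identical(cls$outcome, "classified")
  expect_equal(cls$at_risk, 1)  # 227 mg/dl = 5.87 mmol/L >= 5.2
  expect_equal(cls$value, 227 / 38.67, tolerance = 1e-12)
  expect_match(cls$conversions_performed, "milligram-per-deciliter")
  # stored unit untouched
  expect_identical(get_quantity(t2, "SerumCholesterolConcentration")$unit,
                   "milligram-per-deciliter")

  # inclusive at-risk boundary, strict complement
  expect_equal(classify_binary(make_record(sbp = 140),
                               mod$sbp)$at_risk, 1)
  expect_equal(classify_binary(make_record(sbp = 139.99),
                               mod$sbp)$at_risk, 0)

  # value in a printed-guideline hole -> explicit gap outcome
  gap <- classify_binary(
    make_record(chol = 5.1, conc_unit = "milli-mole-per-liter"),
    builtin_models("aha")$aha_chol_mmol)
  expect_identical(gap$outcome, "gap")
  expect_identical(gap$label, "unclassified: gap")
  expect_true(is.na(gap$at_risk))

  # missing attribute -> insufficient data, not an error
  expect_identical(classify_binary(make_record(sbp = 120),
                                   mod$chol)$outcome,
                   "insufficient_data")
})

test_that("classification is invariant under unit conversion of the data", {
  mod <- builtin_models("modified")
  set.seed(99)
  for (i in 1:50) {
    chol_mgdl <- runif(1, 100, 400)
    r_mgdl <- make_record(chol = chol_mgdl)
    r_mmol <- make_record(chol = chol_mgdl / 38.67,
                          conc_unit = "milli-mole-per-liter")
    a <- classify_binary(r_mgdl, mod$chol)
    b <- classify_binary(r_mmol, mod$chol)
    expect_identical(a$at_risk, b$at_risk)
  }
  # pressure: mmHg vs kPa
  r_kpa <- patient_record("p")
  r_kpa <- set_attribute(r_kpa, "SystolicBloodPressure",
                         quantity(18.7, "kilopascal"))
  expect_equal(classify_binary(r_kpa, mod$sbp)$at_risk, 1)
})

test_that("sex-specific HDL overrides apply", {
  m <- builtin_models("aha")$aha_hdl_mgdl_sex
  male45 <- make_record(hdl = 45, sex = "male")
  female45 <- make_record(hdl = 45, sex = "female")
  expect_equal(classify_binary(male45, m)$at_risk, 0)
  expect_equal(classify_binary(female45, m)$at_risk, 1)
})

test_that("joint blood-pressure staging follows the published table", {
  stage <- function(s, d) classify_bp_stage(make_record(sbp = s, dbp = d))
  x <- stage(128, 80.1)
  expect_identical(x$stage, "Pre-hypertension")
  expect_equal(x$at_risk, 0)
  x <- stage(150, 85)
  expect_identical(x$stage, "Isolated systolic hypertension")
  expect_equal(x$at_risk, 1)
  expect_identical(stage(119, 79)$stage, "Normal")
  expect_identical(stage(119, 85)$stage, "Pre-hypertension")  # DBP worse
  expect_identical(stage(145, 95)$stage, "Stage 1")
  expect_identical(stage(165, 95)$stage, "Stage 2")
  expect_identical(stage(150, 102)$stage, "Stage 2")
  expect_equal(stage(145, 95)$at_risk, 1)
  expect_identical(stage(85, 70)$outcome, "below-range")
  expect_identical(stage(120, 55)$outcome, "below-range")
  expect_identical(classify_bp_stage(make_record(sbp = 120))$outcome,
                   "insufficient_data")
})

test_that("lift derives missing attributes once and is idempotent", {
  mod <- builtin_models("modified")

  # composition: lift == derive_bmi then classify
  hm <- make_record(height = 1.70, mass = 80)
  lifted <- lift(hm, "bmi", models = mod)
  direct <- classify_binary(derive_bmi(hm), mod$bmi)
  expect_equal(lifted$results$bmi$at_risk, direct$at_risk)
  expect_identical(lifted$provenance, "derived BodyMassIndex")

  # full record, all seven targets: each derivation performed once
  full <- make_record(sbp = 128, dbp = 80.1, chol = 227, hdl = 55,
                      tg = 84, age = 77, height = 1.8288, mass = 78.1818,
                      sex = "male")
  keys <- binary_model_keys(mod)
  out <- lift(full, keys, models = mod)
  expect_length(out$results, 7)
  flags <- vapply(out$results, `[[`, numeric(1), "at_risk")
  expect_equal(unname(flags[keys]), c(0, 0, 1, 0, 0, 0, 0))
  expect_equal(sort(out$provenance),
               sort(c("derived BodyMassIndex",
                      "derived SerumLDLCholesterolConcentration")))

  # idempotence: lifting the lifted record changes nothing
  out2 <- lift(out$record, keys, models = mod)
  expect_equal(out2$record, out$record)
  expect_identical(out2$provenance, character(0))

  # underivable target -> per-target insufficient data
  no_tg <- make_record(chol = 227, hdl = 55)
  res <- lift(no_tg, "ldl", models = mod)
  expect_identical(res$results$ldl$outcome, "insufficient_data")
})

test_that("validate_model enumerates gaps and overlaps", {
  aha <- builtin_models("aha")
  v <- validate_model(aha$aha_chol_mmol)
  expect_length(v$gaps, 1)
  expect_equal(v$gaps[[1]]$lower, 5)
  expect_equal(v$gaps[[1]]$upper, 5.2)
  expect_true(v$gaps[[1]]$lower_uncovered)   # 5.0 itself unclassified
  expect_false(v$gaps[[1]]$upper_uncovered)  # 5.2 is at-risk inclusive
  expect_length(v$overlaps, 0)

  # binary models partition the line
  for (k in binary_model_keys(aha)) {
    v <- validate_model(aha[[k]])
    expect_length(v$gaps, 0)
    expect_length(v$overlaps, 0)
  }

  # two bands sharing an inclusive endpoint overlap
  m <- risk_model("overlapping", "BodyMassIndex",
                  "kilogram-per-meter-squared",
                  list(band(-Inf, 25, "a", 0, upper_inclusive = TRUE),
                       band(25, Inf, "b", 1, lower_inclusive = TRUE)))
  v <- validate_model(m)
  expect_length(v$overlaps, 1)
  expect_length(v$gaps, 0)

  # printed BMI table has the decimal-grid holes
  v <- validate_model(aha$aha_bmi_bands)
  gl <- vapply(v$gaps, `[[`, numeric(1), "lower")
  expect_equal(gl, c(24.9, 29.9, 39.9))
})

test_that("model sets serialize to config and back", {
  mod <- builtin_models("modified")
  path <- withr::local_tempfile(fileext = ".json")
  write_model_set(mod, path)
  back <- read_model_set(path)
  expect_setequal(names(back), names(mod))
  expect_identical(attr(back, "set"), "modified")
  t2 <- table2_record()
  for (k in binary_model_keys(mod)) {
    expect_identical(classify_binary(t2, back[[k]])$at_risk,
                     classify_binary(t2, mod[[k]])$at_risk, info = k)
  }
  # sex overrides survive
  f45 <- make_record(hdl = 45, sex = "female")
  expect_equal(classify_binary(f45, back$aha_hdl_mgdl_sex)$at_risk, 1)
})
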
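# Shared fixtures, all built in code at test time.

# The legacy spreadsheet's printed first row.
table2_csv <- function() {
  c(paste("SBP,DBP,TOTALCHOL,HDL,TG,AGE,GENDER,HEIGHT,WEIGHT,TG GR",
          "HDL GR,LDL GR,CHOL GR,BMI GR,DBP GR,SBP GR,RISK GR", sep = ","),
    "128,80.1,227,55,84,77,M,1.8288,78.1818,0,0,0,1,0,0,0,1")
}

table2_record <- function() read_legacy_table(table2_csv())[[1]]

# A record built directly from quantities (mg/dl lipid panel).
make_record <- function(id = "r1", sbp = NULL, dbp = NULL, chol = NULL,
                        hdl = NULL, tg = NULL, age = NULL, height = NULL,
                        mass = NULL, sex = NULL, smoker = NULL,
                        diabetic = NULL, bp_treated = NULL,
                        conc_unit = "milligram-per-deciliter") {
  rec <- patient_record(id, smoker = smoker, diabetic = diabetic,
                        bp_treated = bp_treated)
  add <- function(rec, mclass, v, unit) {
    if (is.null(v)) rec else set_attribute(rec, mclass, quantity(v, unit))
  }
  rec <- add(rec, "SystolicBloodPressure", sbp,
             "millimeter-of-mercury-column")
  rec <- add(rec, "DiastolicBloodPressure", dbp,
             "millimeter-of-mercury-column")
  rec <- add(rec, "SerumCholesterolConcentration", chol, conc_unit)
  rec <- add(rec, "SerumHDLCholesterolConcentration", hdl, conc_unit)
  rec <- add(rec, "SerumTriglycerideConcentration", tg, conc_unit)
  rec <- add(rec, "Age", age, "year")
  rec <- add(rec, "Height", height, "meter")
  rec <- add(rec, "Mass", mass, "kilogram")
  if (!is.null(sex)) rec <- set_sex(rec, sex)
  rec
}

# Independent brute-force threshold scan over observed values and
# midpoints (the oracle recover_threshold is checked against).
brute_force_threshold <- function(values, labels, direction) {
  ge <- identical(direction, "at_risk_if_ge")
  sv <- sort(unique(values))
  mids <- if (length(sv) > 1) (sv[-1] + sv[-length(sv)]) / 2 else numeric(0)
  cand <- sort(unique(c(sv, mids)))
  acc <- vapply(cand, function(b) {
    pred <- if (ge) as.numeric(values >= b) else as.numeric(values <= b)
    mean(pred == labels)
  }, numeric(1))
  list(best_acc = max(acc), cand = cand, acc = acc)
}
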
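# Derivation services: algorithms that lift core measurements into the
# derived measurement classes (BMI, Friedewald LDL, Framingham score).

#' Derive body mass index
#'
#' BMI = mass\[kg\] / height\[m\]^2, attached as a BodyMassIndex attribute
#' in kilogram-per-meter-squared. Inputs in any convertible unit (e.g.
#' height in cm) give the same result; original attributes are untouched.
#'
#' @param record A [patient_record()] carrying Height and Mass.
#' @param registry A [unit_registry()].
#' @return The record augmented with a BodyMassIndex attribute.
#' @export
derive_bmi <- function(record, registry = builtin_units()) {
  h <- get_quantity(record, "Height", "meter", registry = registry)
  m <- get_quantity(record, "Mass", "kilogram", registry = registry)
  if (is.null(h) || is.null(m)) {
    stop("derive_bmi needs Height and Mass", call. = FALSE)
  }
  if (h$value <= 0) stop("non-positive height", call. = FALSE)
  set_attribute(record, "BodyMassIndex",
                quantity(m$value / h$value^2, "kilogram-per-meter-squared"))
}

# Friedewald constants by working unit system.
.FRIEDEWALD_K <- c("milligram-per-deciliter" = 0.20,
                   "milli-mole-per-liter" = 0.45)

#' Derive LDL cholesterol by the Friedewald equation
#'
#' LDL = total cholesterol - HDL - k * triglycerides, computed in the
#' unit system of the stored total-cholesterol measurement: k = 0.20 when
#' working in mg/dl, 0.45 in mmol/l — the correct constant is selected
#' automatically from the units. HDL and triglycerides are converted into
#' the working system as needed.
#'
#' @param record A [patient_record()] carrying total cholesterol, HDL and
#'   triglycerides.
#' @param tg_guard When TRUE, refuse triglycerides above 400 mg/dl
#'   (standard Friedewald validity limit); off by default.
#' @param registry A [unit_registry()].
#' @return The record augmented with a SerumLDLCholesterolConcentration
#'   attribute in the working unit.
#' @export
derive_ldl <- function(record, tg_guard = FALSE,
                       registry = builtin_units()) {
  chol <- get_quantity(record, "SerumCholesterolConcentration",
                       registry = registry)
  if (is.null(chol)) stop("derive_ldl needs total cholesterol", call. = FALSE)
  u <- resolve_unit(registry, chol$unit)
  working <- if (identical(u$quality, "molar-concentration")) {
    "milli-mole-per-liter"
  } else {
    "milligram-per-deciliter"
  }
  k <- .FRIEDEWALD_K[[working]]
  c_w <- get_quantity(record, "SerumCholesterolConcentration", working,
                      registry = registry)
  h_w <- get_quantity(record, "SerumHDLCholesterolConcentration", working,
                      registry = registry)
  t_w <- get_quantity(record, "SerumTriglycerideConcentration", working,
                      registry = registry)
  if (is.null(h_w) || is.null(t_w)) {
    stop("derive_ldl needs HDL and triglycerides", call. = FALSE)
  }
  if (tg_guard) {
    tg_mgdl <- convert_quantity(t_w, "milligram-per-deciliter",
                                analyte = "triglyceride",
                                registry = registry)$value
    if (tg_mgdl > 400) {
      stop("triglycerides above 400 mg/dl: Friedewald estimate invalid",
           call. = FALSE)
    }
  }
  ldl <- c_w$value - h_w$value - k * t_w$value
  if (ldl < 0) {
    stop("computed LDL is negative: implausible inputs", call. = FALSE)
  }
  set_attribute(record, "SerumLDLCholesterolConcentration",
                quantity(ldl, working))
}

#' Framingham general-CVD risk profile (men)
#'
#' Inputs of the men's general cardiovascular disease scoring table. Only
#' the men's table is supported; age must be at least 30 (the lowest
#' scored band).
#'
#' @param age Age in years (numeric or [quantity()] in a time unit).
#' @param total_cholesterol,hdl Concentrations (numeric = mg/dl, or
#'   [quantity()] in any bridged concentration unit).
#' @param sbp Systolic blood pressure (numeric = mmHg, or [quantity()]).
#' @param bp_treated,smoker,diabetic Logical.
#' @param sex Only "male".
#' @return An object of class `framingham_profile`.
#' @export
framingham_profile <- function(age, total_cholesterol, hdl, sbp,
                               bp_treated = FALSE, smoker = FALSE,
                               diabetic = FALSE, sex = "male") {
  if (!identical(sex, "male")) {
    stop("only the men's general-CVD table is supported", call. = FALSE)
  }
  as_q <- function(x, unit) if (inherits(x, "quantity")) x else quantity(x, unit)
  age_q <- as_q(age, "year")
  if (convert_quantity(age_q, "year")$value < 30) {
    stop("age below 30 is outside the scored bands", call. = FALSE)
  }
  structure(
    list(age = age_q,
         total_cholesterol = as_q(total_cholesterol,
                                  "milligram-per-deciliter"),
         hdl = as_q(hdl, "milligram-per-deciliter"),
         sbp = as_q(sbp, "millimeter-of-mercury-column"),
         bp_treated = isTRUE(bp_treated), smoker = isTRUE(smoker),
         diabetic = isTRUE(diabetic), sex = sex),
    class = "framingham_profile"
  )
}

# Half-open band lookup: breaks are the printed lower edges; a value in
# [breaks[i], breaks[i+1]) scores points[i].
band_points <- function(x, breaks, points) {
  idx <- findInterval(x, breaks)
  points[[idx + 1L]]
}

#' Per-factor Framingham points (men's general-CVD table)
#'
#' Row lookup of the printed scoring table: age bands 30-34 (0) through
#' 75+ (15); HDL 60+ (-2) down to <35 (+2); total cholesterol <160 (0) to
#' 280+ (+4); SBP by treatment status; smoker +4; diabetic +3.
#'
#' @param profile A [framingham_profile()].
#' @param registry A [unit_registry()].
#' @return An object of class `framingham_result` with fields
#'   `per_factor_points`, `total_points`, `ten_year_risk`, `category`.
#' @export
framingham_points <- function(profile, registry = builtin_units()) {
  stopifnot(inherits(profile, "framingham_profile"))
  age <- convert_quantity(profile$age, "year", registry = registry)$value
  hdl <- convert_quantity(profile$hdl, "milligram-per-deciliter",
                          analyte = "hdl", registry = registry)$value
  chol <- convert_quantity(profile$total_cholesterol,
                           "milligram-per-deciliter",
                           analyte = "total-cholesterol",
                           registry = registry)$value
  sbp <- convert_quantity(profile$sbp, "millimeter-of-mercury-column",
                          registry = registry)$value
  if (age < 30) stop("age below 30 is outside the scored bands", call. = FALSE)

  pts <- c(
    age = band_points(age, c(30, 35, 40, 45, 50, 55, 60, 65, 70, 75),
                      c(NA, 0, 2, 5, 6, 8, 10, 11, 12, 14, 15)),
    hdl = band_points(hdl, c(35, 45, 50, 60), c(2, 1, 0, -1, -2)),
    total_cholesterol = band_points(chol, c(160, 200, 240, 280),
                                    c(0, 1, 2, 3, 4)),
    sbp = if (profile$bp_treated) {
      band_points(sbp, c(120, 130, 140, 160), c(0, 2, 3, 4, 5))
    } else {
      band_points(sbp, c(120, 130, 140, 160), c(-2, 0, 1, 2, 3))
    },
    smoker = if (profile$smoker) 4 else 0,
    diabetic = if (profile$diabetic) 3 else 0
  )
  total <- as.integer(sum(pts))
  structure(
    list(per_factor_points = pts, total_points = total,
         ten_year_risk = framingham_percent(total),
         category = framingham_category(total)),
    class = "framingham_result"
  )
}

#' @export
print.framingham_result <- function(x, ...) {
  cat("<framingham_result> total", x$total_points, "points;",
      "10-year risk", format_risk(x$ten_year_risk), ";",
      "category", x$category, "\n")
  cat("  points:", paste(names(x$per_factor_points), x$per_factor_points,
                         sep = "=", collapse = " "), "\n")
  invisible(x)
}

format_risk <- function(r) {
  paste0(switch(r$comparator, "<" = "<", ">=" = "≥", ""), r$percent, "%")
}

#' Total Framingham points to 10-year general-CVD risk percent
#'
#' Table lookup; the open-ended rows are returned as bounds (comparator
#' `"<"` for under 9 points, `">="` for 25 or more), not point values.
#'
#' @param total_points Integer total score.
#' @return List with `percent` (number as printed) and `comparator`
#'   (one of `"<"`, `"="`, `">="`).
#' @export
framingham_percent <- function(total_points) {
  p <- total_points
  if (p < 9) return(list(percent = 1, comparator = "<"))
  if (p >= 25) return(list(percent = 30, comparator = ">="))
  pct <- c(`9` = 1, `10` = 1, `11` = 1, `12` = 1, `13` = 2, `14` = 2,
           `15` = 3, `16` = 4, `17` = 5, `18` = 6, `19` = 8, `20` = 11,
           `21` = 14, `22` = 17, `23` = 22, `24` = 27)
  list(percent = unname(pct[[as.character(as.integer(p))]]),
       comparator = "=")
}

#' Ternary risk category from total Framingham points
#'
#' The Canadian quantization: 9 points or fewer is low, 10-19 medium,
#' 20 or more high.
#'
#' @param total_points Integer total score.
#' @return `"low"`, `"medium"` or `"high"`.
#' @export
framingham_category <- function(total_points) {
  if (total_points <= 9) "low" else if (total_points <= 19) "medium" else "high"
}

#' Derive the Framingham general-CVD score for a record
#'
#' Builds the profile from the record's Age, total cholesterol, HDL and
#' SBP attributes plus smoking/diabetes status (which must be present:
#' they are never assumed), scores it, and attaches the total as a
#' GeneralCVDFraminghamRiskScore attribute. `bp_treated` defaults to
#' FALSE when absent. Female and missing-sex records are rejected (only
#' the men's table is printed).
#'
#' @param record A [patient_record()].
#' @param registry A [unit_registry()].
#' @return List with `record` (augmented) and `result`
#'   (a `framingham_result`).
#' @export
derive_framingham <- function(record, registry = builtin_units()) {
  age <- get_quantity(record, "Age", registry = registry)
  chol <- get_quantity(record, "SerumCholesterolConcentration",
                       registry = registry)
  hdl <- get_quantity(record, "SerumHDLCholesterolConcentration",
                      registry = registry)
  sbp <- get_quantity(record, "SystolicBloodPressure", registry = registry)
  if (is.null(age) || is.null(chol) || is.null(hdl) || is.null(sbp)) {
    stop("framingham needs Age, total cholesterol, HDL and SBP",
         call. = FALSE)
  }
  if (!identical(get_sex(record), "male")) {
    stop("only male records can be scored (men's table)", call. = FALSE)
  }
  if (is.null(record$smoker) || is.null(record$diabetic)) {
    stop("framingham needs smoking and diabetes status", call. = FALSE)
  }
  prof <- framingham_profile(
    age, chol, hdl, sbp,
    bp_treated = isTRUE(record$bp_treated),
    smoker = record$smoker, diabetic = record$diabetic
  )
  res <- framingham_points(prof, registry = registry)
  record <- set_attribute(record, "GeneralCVDFraminghamRiskScore",
                          quantity(res$total_points, "dimensionless"))
  list(record = record, result = res)
}
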
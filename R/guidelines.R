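# Declarative band-based guideline models and the lifting classifier.
# Boundary convention (taken from the published restriction classes): the
# at-risk side is inclusive (>= threshold, or <= for HDL), the low side
# strict.

#' Construct a value band
#'
#' @param lower,upper Band edges (`-Inf`/`Inf` allowed).
#' @param label Human-readable interpretation.
#' @param at_risk 0 or 1: the binary flag this band maps to.
#' @param lower_inclusive,upper_inclusive Edge inclusivity.
#' @return An object of class `risk_band`.
#' @export
band <- function(lower = -Inf, upper = Inf, label, at_risk,
                 lower_inclusive = TRUE, upper_inclusive = FALSE) {
  stopifnot(at_risk %in% c(0, 1))
  at_risk <- as.numeric(at_risk)
  if (!(lower < upper ||
        (lower == upper && lower_inclusive && upper_inclusive))) {
    stop("band must satisfy lower < upper (or a doubly-inclusive point)",
         call. = FALSE)
  }
  structure(list(lower = lower, upper = upper, label = label,
                 at_risk = at_risk,
                 lower_inclusive = isTRUE(lower_inclusive) && is.finite(lower),
                 upper_inclusive = isTRUE(upper_inclusive) && is.finite(upper)),
            class = "risk_band")
}

in_band <- function(x, b) {
  lo <- if (b$lower_inclusive) x >= b$lower else x > b$lower
  hi <- if (b$upper_inclusive) x <= b$upper else x < b$upper
  lo && hi
}

#' Construct a declarative risk model
#'
#' An ordered set of value bands over one measurement class, with a
#' canonical unit the measurement is converted into before matching.
#'
#' @param name Model identifier.
#' @param mclass Measurement class the model classifies.
#' @param canonical_unit Unit name the bands are expressed in.
#' @param bands List of [band()]s (non-overlapping).
#' @param analyte Analyte tag for concentration bridging (default: the
#'   class's own analyte).
#' @param sex_overrides Optional named list (`male`/`female`) of band
#'   lists replacing `bands` for that sex.
#' @param flag_key Expert-flag key this model corresponds to (e.g.
#'   `"CHOL"`); used by concordance evaluation.
#' @return An object of class `risk_model`.
#' @export
risk_model <- function(name, mclass, canonical_unit, bands,
                       analyte = class_analyte(mclass),
                       sex_overrides = NULL, flag_key = NULL) {
  structure(list(name = name, mclass = mclass,
                 canonical_unit = canonical_unit, bands = bands,
                 analyte = analyte, sex_overrides = sex_overrides,
                 flag_key = flag_key),
            class = "risk_model")
}

#' @export
print.risk_model <- function(x, ...) {
  cat("<risk_model> ", x$name, " on ", x$mclass, " [", x$canonical_unit,
      "]\n", sep = "")
  for (b in x$bands) {
    cat(sprintf("  %s%s, %s%s  %-22s at_risk=%d\n",
                if (b$lower_inclusive) "[" else "(", format(b$lower),
                format(b$upper), if (b$upper_inclusive) "]" else ")",
                b$label, b$at_risk))
  }
  invisible(x)
}

# binary >=/<= models share this shape
binary_ge <- function(name, mclass, unit, threshold, flag_key) {
  risk_model(name, mclass, unit,
             list(band(-Inf, threshold, "not-at-risk", 0,
                       upper_inclusive = FALSE),
                  band(threshold, Inf, "at-risk", 1,
                       lower_inclusive = TRUE)),
             flag_key = flag_key)
}

binary_le <- function(name, mclass, unit, threshold, flag_key) {
  risk_model(name, mclass, unit,
             list(band(-Inf, threshold, "at-risk", 1,
                       upper_inclusive = TRUE),
                  band(threshold, Inf, "not-at-risk", 0,
                       lower_inclusive = FALSE)),
             flag_key = flag_key)
}

#' Built-in guideline model registry
#'
#' `set = "aha"` carries the official binary cutoffs (SBP >= 140 mmHg,
#' DBP >= 90 mmHg, total cholesterol >= 5.0 mmol/L, HDL <= 1.03 mmol/L,
#' triglycerides >= 2.26 mmol/L, BMI >= 25 kg/m2, LDL >= 160 mg/dl).
#' `set = "modified"` carries the clinician-personalized thresholds
#' (cholesterol 5.2, HDL 0.89, triglycerides 2.63, BMI 26), blood
#' pressure and LDL unchanged. Both sets also ship the multi-band models
#' exactly as printed in the guideline tables (including their gaps,
#' which [validate_model()] reports) plus a sex-specific mg/dl HDL model.
#'
#' @param set `"aha"` or `"modified"`.
#' @return Named list of [risk_model()]s with attribute `set`; the seven
#'   binary models are keyed `sbp`, `dbp`, `chol`, `hdl`, `tg`, `bmi`,
#'   `ldl`.
#' @export
builtin_models <- function(set = c("aha", "modified")) {
  set <- match.arg(set)
  modified <- identical(set, "modified")
  models <- list(
    sbp = binary_ge("sbp", "SystolicBloodPressure",
                    "millimeter-of-mercury-column", 140, "SBP"),
    dbp = binary_ge("dbp", "DiastolicBloodPressure",
                    "millimeter-of-mercury-column", 90, "DBP"),
    chol = binary_ge("chol", "SerumCholesterolConcentration",
                     "milli-mole-per-liter", if (modified) 5.2 else 5.0,
                     "CHOL"),
    hdl = binary_le("hdl", "SerumHDLCholesterolConcentration",
                    "milli-mole-per-liter", if (modified) 0.89 else 1.03,
                    "HDL"),
    tg = binary_ge("tg", "SerumTriglycerideConcentration",
                   "milli-mole-per-liter", if (modified) 2.63 else 2.26,
                   "TG"),
    bmi = binary_ge("bmi", "BodyMassIndex", "kilogram-per-meter-squared",
                    if (modified) 26 else 25, "BMI"),
    ldl = binary_ge("ldl", "SerumLDLCholesterolConcentration",
                    "milligram-per-deciliter", 160, "LDL"),

    # guideline tables as printed (with their gaps)
    aha_chol_mmol = risk_model(
      "aha_chol_mmol", "SerumCholesterolConcentration",
      "milli-mole-per-liter",
      list(band(-Inf, 5, "desirable", 0),
           band(5.2, 6.2, "borderline-high-risk", 1,
                lower_inclusive = TRUE, upper_inclusive = TRUE),
           band(6.2, Inf, "high-risk", 1, lower_inclusive = FALSE)),
      flag_key = "CHOL"),
    aha_hdl_mmol = risk_model(
      "aha_hdl_mmol", "SerumHDLCholesterolConcentration",
      "milli-mole-per-liter",
      list(band(-Inf, 1.03, "low-hdl-heightened-risk", 1),
           band(1.03, 1.55, "medium-hdl", 0,
                lower_inclusive = TRUE, upper_inclusive = TRUE),
           band(1.55, Inf, "high-hdl-optimal", 0, lower_inclusive = FALSE)),
      flag_key = "HDL"),
    aha_hdl_mgdl_sex = risk_model(
      "aha_hdl_mgdl_sex", "SerumHDLCholesterolConcentration",
      "milligram-per-deciliter",
      list(band(-Inf, 40, "low-hdl-heightened-risk", 1),
           band(40, 59, "medium-hdl", 0,
                lower_inclusive = TRUE, upper_inclusive = TRUE),
           band(60, Inf, "high-hdl-optimal", 0, lower_inclusive = FALSE)),
      sex_overrides = list(
        female = list(band(-Inf, 50, "low-hdl-heightened-risk", 1),
                      band(50, 59, "medium-hdl", 0,
                           lower_inclusive = TRUE, upper_inclusive = TRUE),
                      band(60, Inf, "high-hdl-optimal", 0,
                           lower_inclusive = FALSE))),
      flag_key = "HDL"),
    aha_tg_mmol = risk_model(
      "aha_tg_mmol", "SerumTriglycerideConcentration",
      "milli-mole-per-liter",
      list(band(-Inf, 1.69, "normal-low-risk", 0),
           band(1.70, 2.25, "borderline-high", 0,
                lower_inclusive = TRUE, upper_inclusive = TRUE),
           band(2.26, 5.65, "high", 1,
                lower_inclusive = TRUE, upper_inclusive = TRUE),
           band(5.65, Inf, "very-high-risk", 1, lower_inclusive = FALSE)),
      flag_key = "TG"),
    aha_bmi_bands = risk_model(
      "aha_bmi_bands", "BodyMassIndex", "kilogram-per-meter-squared",
      list(band(-Inf, 18.5, "underweight", 0),
           band(18.5, 24.9, "healthy-weight", 0,
                lower_inclusive = TRUE, upper_inclusive = TRUE),
           band(25.0, 29.9, "overweight", 1,
                lower_inclusive = TRUE, upper_inclusive = TRUE),
           band(30, 39.9, "obese", 1,
                lower_inclusive = TRUE, upper_inclusive = TRUE),
           band(40, Inf, "morbidly-obese", 1, lower_inclusive = TRUE)),
      flag_key = "BMI"),
    aha_ldl_mgdl = risk_model(
      "aha_ldl_mgdl", "SerumLDLCholesterolConcentration",
      "milligram-per-deciliter",
      list(band(-Inf, 129, "desirable", 0),
           band(130, 159, "borderline-high-risk", 0,
                lower_inclusive = TRUE, upper_inclusive = TRUE),
           band(160, Inf, "high-risk", 1, lower_inclusive = FALSE)),
      flag_key = "LDL")
  )
  attr(models, "set") <- set
  models
}

#' Binary model keys of a model registry
#' @param models A registry from [builtin_models()] or [read_model_set()].
#' @export
binary_model_keys <- function(models) {
  intersect(c("sbp", "dbp", "chol", "hdl", "tg", "bmi", "ldl"),
            names(models))
}

#' Classify a record against a risk model
#'
#' The stored measurement is converted (analyte-aware) to the model's
#' canonical unit — the stored unit is never mutated — and matched to a
#' band. A value falling in a gap of the printed guideline yields an
#' explicit `"gap"` outcome, never a silent default; a missing attribute
#' yields `"insufficient_data"` (use [lift()] to derive it first).
#'
#' @param record A [patient_record()].
#' @param model A [risk_model()].
#' @param registry A [unit_registry()].
#' @return An object of class `classification`: fields `record_id`,
#'   `model`, `outcome` (`"classified"`, `"gap"`, `"insufficient_data"`),
#'   `label`, `at_risk`, `value` (in canonical unit),
#'   `conversions_performed`, `derivations_performed`.
#' @export
classify_binary <- function(record, model, registry = builtin_units()) {
  stopifnot(inherits(model, "risk_model"))
  res <- structure(
    list(record_id = record$record_id, model = model$name,
         outcome = "insufficient_data", label = NA_character_,
         at_risk = NA_real_, value = NA_real_,
         conversions_performed = character(0),
         derivations_performed = character(0)),
    class = "classification"
  )
  stored <- get_quantity(record, model$mclass, registry = registry)
  if (is.null(stored)) return(res)
  q <- get_quantity(record, model$mclass, target_unit = model$canonical_unit,
                    analyte = model$analyte, registry = registry)
  if (!identical(stored$unit,
                 resolve_unit(registry, model$canonical_unit)$name)) {
    res$conversions_performed <-
      sprintf("%s: %s -> %s", model$mclass, stored$unit,
              model$canonical_unit)
  }
  bands <- model$bands
  sx <- get_sex(record)
  if (!is.null(model$sex_overrides) && !is.null(sx) &&
      !is.null(model$sex_overrides[[sx]])) {
    bands <- model$sex_overrides[[sx]]
  }
  res$value <- q$value
  for (b in bands) {
    if (in_band(q$value, b)) {
      res$outcome <- "classified"
      res$label <- b$label
      res$at_risk <- b$at_risk
      return(res)
    }
  }
  res$outcome <- "gap"
  res$label <- "unclassified: gap"
  res
}

#' @export
print.classification <- function(x, ...) {
  cat("<classification> ", x$record_id, " / ", x$model, ": ", x$outcome,
      sep = "")
  if (identical(x$outcome, "classified")) {
    cat(" [", x$label, ", at_risk=", x$at_risk, "]", sep = "")
  }
  cat("\n")
  invisible(x)
}

# blood-pressure stage tables (half-open printed bands, mmHg)
.SBP_STAGES <- list(breaks = c(90, 120, 140, 160),
                    labels = c(NA, "Normal", "Pre-hypertension",
                               "Stage 1", "Stage 2"))
.DBP_STAGES <- list(breaks = c(60, 80, 90, 100),
                    labels = c(NA, "Normal", "Pre-hypertension",
                               "Stage 1", "Stage 2"))
.STAGE_SEVERITY <- c("Normal" = 1, "Pre-hypertension" = 2,
                     "Stage 1" = 3, "Stage 2" = 4)

#' Joint blood-pressure staging
#'
#' Applies the five-category blood-pressure guideline jointly: isolated
#' systolic hypertension iff SBP >= 140 with DBP < 90; otherwise the more
#' severe of the SBP and DBP stages. Normal and Pre-hypertension map to
#' not-at-risk. Pressures below the tables' lower bounds (SBP < 90 or
#' DBP < 60) yield a `"below-range"` outcome.
#'
#' @param record A [patient_record()] with SBP and DBP.
#' @param registry A [unit_registry()].
#' @return List with `outcome`, `stage`, `at_risk`.
#' @export
classify_bp_stage <- function(record, registry = builtin_units()) {
  sbp <- get_quantity(record, "SystolicBloodPressure",
                      "millimeter-of-mercury-column", registry = registry)
  dbp <- get_quantity(record, "DiastolicBloodPressure",
                      "millimeter-of-mercury-column", registry = registry)
  if (is.null(sbp) || is.null(dbp)) {
    return(list(outcome = "insufficient_data", stage = NA_character_,
                at_risk = NA_real_))
  }
  s <- sbp$value
  d <- dbp$value
  if (s < 90 || d < 60) {
    return(list(outcome = "below-range", stage = NA_character_,
                at_risk = NA_real_))
  }
  if (s >= 140 && d < 90) {
    return(list(outcome = "classified",
                stage = "Isolated systolic hypertension", at_risk = 1))
  }
  s_stage <- .SBP_STAGES$labels[[findInterval(s, .SBP_STAGES$breaks) + 1L]]
  d_stage <- .DBP_STAGES$labels[[findInterval(d, .DBP_STAGES$breaks) + 1L]]
  stage <- if (.STAGE_SEVERITY[[s_stage]] >= .STAGE_SEVERITY[[d_stage]]) {
    s_stage
  } else {
    d_stage
  }
  list(outcome = "classified", stage = stage,
       at_risk = if (stage %in% c("Normal", "Pre-hypertension")) 0 else 1)
}

# measurement classes derivable by the lifting layer, with dependencies
.DERIVABLE <- list(
  BodyMassIndex = c("Height", "Mass"),
  SerumLDLCholesterolConcentration =
    c("SerumCholesterolConcentration", "SerumHDLCholesterolConcentration",
      "SerumTriglycerideConcentration"),
  GeneralCVDFraminghamRiskScore =
    c("Age", "SerumCholesterolConcentration",
      "SerumHDLCholesterolConcentration", "SystolicBloodPressure")
)

#' Lift a record through derivations and classify targets
#'
#' Resolves the derivation dependency graph (BMI from height and mass;
#' LDL from the lipid panel; the Framingham score from age, lipids, SBP
#' and smoking/diabetes status), derives each missing derivable attribute
#' exactly once, classifies every target, and records provenance. A
#' record already carrying a derived attribute is not re-derived, so
#' lifting is idempotent. Targets whose inputs are missing get a
#' per-target `"insufficient_data"` outcome (never an error).
#'
#' @param record A [patient_record()].
#' @param targets Character vector of model keys/names in `models`, or
#'   `"framingham"` for the ternary score.
#' @param models A model registry ([builtin_models()]).
#' @param registry A [unit_registry()].
#' @return List with `record` (augmented), `results` (named by target;
#'   [classify_binary()] results, or for `"framingham"` a list with
#'   `outcome`, `total_points`, `category`, `ternary`, `ten_year_risk`),
#'   and `provenance` (character vector of derivations performed).
#' @export
lift <- function(record, targets, models = builtin_models("modified"),
                 registry = builtin_units()) {
  provenance <- character(0)
  derive_once <- function(mclass) {
    if (!is.null(record$attributes[[mclass]])) return(TRUE)
    deps <- .DERIVABLE[[mclass]]
    if (is.null(deps)) return(FALSE)
    ok <- all(vapply(deps, function(d) !is.null(record$attributes[[d]]),
                     logical(1)))
    if (!ok) return(FALSE)
    out <- tryCatch(switch(
      mclass,
      BodyMassIndex = derive_bmi(record, registry = registry),
      SerumLDLCholesterolConcentration =
        derive_ldl(record, registry = registry),
      GeneralCVDFraminghamRiskScore =
        derive_framingham(record, registry = registry)$record
    ), error = function(e) NULL)
    if (is.null(out)) return(FALSE)
    record <<- out
    provenance <<- c(provenance, sprintf("derived %s", mclass))
    TRUE
  }

  results <- list()
  for (tg in targets) {
    if (identical(tg, "framingham")) {
      ok <- derive_once("GeneralCVDFraminghamRiskScore")
      if (!ok) {
        results[[tg]] <- list(outcome = "insufficient_data")
        next
      }
      total <- get_quantity(record, "GeneralCVDFraminghamRiskScore")$value
      cat_ <- framingham_category(total)
      results[[tg]] <- list(
        outcome = "classified", total_points = as.integer(total),
        category = cat_,
        ternary = c(low = 1L, medium = 2L, high = 3L)[[cat_]],
        ten_year_risk = framingham_percent(total))
      next
    }
    model <- models[[tg]]
    if (is.null(model)) stop("unknown target model: ", tg, call. = FALSE)
    if (is.null(record$attributes[[model$mclass]])) {
      derive_once(model$mclass)
    }
    cls <- classify_binary(record, model, registry = registry)
    cls$derivations_performed <- provenance
    results[[tg]] <- cls
  }
  list(record = record, results = results, provenance = provenance)
}

#' Enumerate a model's coverage gaps and band overlaps
#'
#' Reports every maximal uncovered interval strictly between the model's
#' outermost declared bounds, and every overlapping band pair. Printed
#' guidelines with a hole in their measurement continuum (e.g. total
#' cholesterol between 5 and 5.2 mmol/L) surface here.
#'
#' @param model A [risk_model()].
#' @return List with `gaps` (each `list(lower, upper, lower_covered_out,
#'   upper_covered_out)` — the uncovered interval includes an endpoint
#'   when the adjacent band excludes it) and `overlaps` (pairs of band
#'   indices).
#' @export
validate_model <- function(model) {
  bands <- model$bands
  ord <- order(vapply(bands, `[[`, numeric(1), "lower"),
               vapply(bands, `[[`, numeric(1), "upper"))
  bands <- bands[ord]
  gaps <- list()
  overlaps <- list()
  if (length(bands) >= 2L) {
    for (i in seq_len(length(bands) - 1L)) {
      a <- bands[[i]]
      b <- bands[[i + 1L]]
      # overlap?
      if (a$upper > b$lower ||
          (a$upper == b$lower && a$upper_inclusive && b$lower_inclusive)) {
        overlaps[[length(overlaps) + 1L]] <-
          list(bands = c(ord[i], ord[i + 1L]),
               labels = c(a$label, b$label))
        next
      }
      # uncovered set between a and b:
      # (a$upper, b$lower) plus endpoints each band excludes
      lo_incl <- !a$upper_inclusive
      hi_incl <- !b$lower_inclusive
      nonempty <- a$upper < b$lower ||
        (a$upper == b$lower && lo_incl && hi_incl)
      if (nonempty) {
        gaps[[length(gaps) + 1L]] <-
          list(lower = a$upper, upper = b$lower,
               lower_uncovered = lo_incl, upper_uncovered = hi_incl)
      }
    }
  }
  list(gaps = gaps, overlaps = overlaps)
}
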
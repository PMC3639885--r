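# Reproducible synthetic cohorts with the legacy dataset's structure and
# a simulated (optionally deviating) rule-following expert labeler. The
# generator stands in for the undeposited cardiovascular cohort: no data
# leaves the package; every fixture is drawn at run time from a seed.

#' Default measurement distributions
#'
#' Truncated normals emulating a plausible post-intervention cardiology
#' cohort: SBP N(130,20) on \[90,220\] mmHg, DBP N(80,12) on \[50,120\],
#' total cholesterol N(210,40) on \[100,400\] mg/dl, HDL N(48,12) on
#' \[20,100\], triglycerides N(140,60) on \[40,400\], glucose N(105,25)
#' on \[60,300\], height N(1.72,0.10) on \[1.4,2.1\] m, weight N(80,15)
#' on \[40,160\] kg, age uniform integer on \[30,85\] years.
#'
#' @return Named list of distribution specs (family, parameters,
#'   truncation range, unit).
#' @export
default_distributions <- function() {
  tn <- function(mean, sd, lower, upper, unit) {
    list(family = "truncnorm", mean = mean, sd = sd, lower = lower,
         upper = upper, unit = unit)
  }
  list(
    SystolicBloodPressure = tn(130, 20, 90, 220,
                               "millimeter-of-mercury-column"),
    DiastolicBloodPressure = tn(80, 12, 50, 120,
                                "millimeter-of-mercury-column"),
    SerumCholesterolConcentration = tn(210, 40, 100, 400,
                                       "milligram-per-deciliter"),
    SerumHDLCholesterolConcentration = tn(48, 12, 20, 100,
                                          "milligram-per-deciliter"),
    SerumTriglycerideConcentration = tn(140, 60, 40, 400,
                                        "milligram-per-deciliter"),
    BloodSugarConcentration = tn(105, 25, 60, 300,
                                 "milligram-per-deciliter"),
    Height = tn(1.72, 0.10, 1.4, 2.1, "meter"),
    Mass = tn(80, 15, 40, 160, "kilogram"),
    Age = list(family = "uniform_int", lower = 30, upper = 85,
               unit = "year")
  )
}

#' Default measurement rounding grids
#'
#' The legacy dataset's apparent precision: integers for SBP and the
#' mg/dl lipid panel, 0.1 mmHg for DBP, 1e-4 for height and weight,
#' integer years for age.
#'
#' @return Named numeric vector of grid steps per measurement class.
#' @export
default_grids <- function() {
  c(SystolicBloodPressure = 1, DiastolicBloodPressure = 0.1,
    SerumCholesterolConcentration = 1,
    SerumHDLCholesterolConcentration = 1,
    SerumTriglycerideConcentration = 1,
    BloodSugarConcentration = 1,
    Height = 1e-4, Mass = 1e-4, Age = 1)
}

#' Specification of a synthetic cohort
#'
#' @param n Number of records (encounters).
#' @param seed Integer RNG seed; the cohort is fully reproducible from it.
#' @param distributions As [default_distributions()].
#' @param sex_fraction_male Probability a record is male.
#' @param smoker_prob,diabetic_prob,treated_prob Status probabilities.
#' @param label_model_set Model set used by the simulated expert
#'   (`"aha"` or `"modified"`).
#' @param deviation_rate Probability each expert binary flag is flipped.
#' @param ternary_deviation_rate Probability the ternary label is shifted
#'   one category (emulating unexplained moderate-band discrepancies).
#' @param missing_rate Per-attribute missingness probability (applied
#'   after labeling).
#' @param grid As [default_grids()].
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 636, seed = 1L,
                        distributions = default_distributions(),
                        sex_fraction_male = 0.7,
                        smoker_prob = 0.3, diabetic_prob = 0.15,
                        treated_prob = 0,
                        label_model_set = "modified",
                        deviation_rate = 0, ternary_deviation_rate = 0,
                        missing_rate = 0, grid = default_grids()) {
  probs <- c(sex_fraction_male, smoker_prob, diabetic_prob, treated_prob,
             deviation_rate, ternary_deviation_rate, missing_rate)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  for (d in distributions) {
    if (!d$family %in% c("truncnorm", "uniform_int")) {
      stop("invalid distribution family: ", d$family, call. = FALSE)
    }
    if (d$lower >= d$upper || d$lower < 0) {
      stop("truncation range must be positive and ordered", call. = FALSE)
    }
  }
  structure(
    list(n = as.integer(n), seed = as.integer(seed),
         distributions = distributions,
         sex_fraction_male = sex_fraction_male,
         smoker_prob = smoker_prob, diabetic_prob = diabetic_prob,
         treated_prob = treated_prob, label_model_set = label_model_set,
         deviation_rate = deviation_rate,
         ternary_deviation_rate = ternary_deviation_rate,
         missing_rate = missing_rate, grid = grid),
    class = "cohort_spec"
  )
}

# inverse-CDF truncated normal: one uniform per draw, reproducible
rtrunc_norm <- function(n, mean, sd, lower, upper) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

snap_to_grid <- function(x, step) round(x / step) * step

#' Label a record the way the simulated expert would
#'
#' The expert follows a guideline model set: the seven binary flags come
#' from [lift()] + classification (LDL and BMI derived on the fly), each
#' independently flipped with probability `deviation_rate`; the ternary
#' label is the Framingham category mapped low/medium/high to 1/2/3,
#' optionally shifted one category with `ternary_deviation_rate`.
#' Consumes the current RNG stream.
#'
#' @param record A [patient_record()].
#' @param models Model registry the expert follows.
#' @param deviation_rate,ternary_deviation_rate Flip/shift probabilities.
#' @param registry A [unit_registry()].
#' @return The record with `expert_flags` and (when derivable)
#'   `expert_ternary` set; underivable flags are left absent.
#' @export
expert_label <- function(record, models = builtin_models("modified"),
                         deviation_rate = 0, ternary_deviation_rate = 0,
                         registry = builtin_units()) {
  keys <- binary_model_keys(models)
  lifted <- lift(record, c(keys, "framingham"), models = models,
                 registry = registry)
  flags <- numeric(0)
  for (k in keys) {
    cls <- lifted$results[[k]]
    if (!identical(cls$outcome, "classified")) next
    flag <- cls$at_risk
    if (deviation_rate > 0 && stats::runif(1) < deviation_rate) {
      flag <- 1 - flag
    }
    flags[[models[[k]]$flag_key]] <- flag
  }
  if (length(flags) > 0L) record$expert_flags <- flags
  fr <- lifted$results[["framingham"]]
  if (identical(fr$outcome, "classified")) {
    tern <- fr$ternary
    if (ternary_deviation_rate > 0 &&
        stats::runif(1) < ternary_deviation_rate) {
      shift <- if (stats::runif(1) < 0.5) -1L else 1L
      tern <- min(3L, max(1L, tern + shift))
    }
    record$expert_ternary <- tern
  }
  record
}

#' Simulate a synthetic cohort
#'
#' Draws the nine core measurements (truncated distributions snapped to
#' the rounding grid), sex and smoker/diabetic/treated status for each
#' record, labels every record with the simulated expert, then applies
#' missingness. Fully reproducible from `spec$seed`; the caller's RNG
#' state is preserved.
#'
#' @param spec A [cohort_spec()].
#' @param registry A [unit_registry()].
#' @return List of [patient_record()]s with expert labels filled.
#' @export
simulate_cohort <- function(spec, registry = builtin_units()) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (spec$n == 0L) return(list())
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (!is.null(old_seed)) {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(spec$seed)

  models <- builtin_models(spec$label_model_set)
  draws <- lapply(spec$distributions, function(d) {
    x <- switch(d$family,
                truncnorm = rtrunc_norm(spec$n, d$mean, d$sd, d$lower,
                                        d$upper),
                uniform_int = floor(stats::runif(spec$n, d$lower,
                                                 d$upper + 1)))
    pmin(pmax(x, d$lower), d$upper)
  })
  sexes <- ifelse(stats::runif(spec$n) < spec$sex_fraction_male,
                  "male", "female")
  smoker <- stats::runif(spec$n) < spec$smoker_prob
  diabetic <- stats::runif(spec$n) < spec$diabetic_prob
  treated <- stats::runif(spec$n) < spec$treated_prob

  records <- vector("list", spec$n)
  for (i in seq_len(spec$n)) {
    rec <- patient_record(sprintf("syn%04d", i))
    for (mclass in names(spec$distributions)) {
      v <- draws[[mclass]][i]
      step <- spec$grid[mclass]
      if (!is.na(step)) v <- snap_to_grid(v, step)
      rec <- set_attribute(rec, mclass,
                           quantity(v, spec$distributions[[mclass]]$unit))
    }
    rec <- set_sex(rec, sexes[i])
    rec$smoker <- smoker[i]
    rec$diabetic <- diabetic[i]
    rec$bp_treated <- treated[i]
    rec <- expert_label(rec, models = models,
                        deviation_rate = spec$deviation_rate,
                        ternary_deviation_rate = spec$ternary_deviation_rate,
                        registry = registry)
    if (spec$missing_rate > 0) {
      for (mclass in names(spec$distributions)) {
        if (stats::runif(1) < spec$missing_rate) {
          rec$attributes[[mclass]] <- NULL
        }
      }
    }
    records[[i]] <- rec
  }
  records
}
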
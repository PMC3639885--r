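# Concordance of automated flags against expert labels, and recovery of
# a clinician's personal cutoff from labeled measurements.

# Derive (once) anything the model needs, then classify; NULL-safe.
classify_with_lift <- function(record, model, models, registry) {
  lifted <- lift(record, model$name, models = models, registry = registry)
  lifted$results[[model$name]]
}

#' Concordance of a model's automated flags with expert labels
#'
#' True-positive rate = percent of expert at-risk records the model also
#' flags at-risk; false-positive rate = percent of expert not-at-risk
#' records the model flags at-risk. Rates are computed over records with
#' both an expert flag and a classifiable value; a zero denominator gives
#' an undefined (NA) rate, never 0.
#'
#' @param records List of [patient_record()]s carrying expert flags.
#' @param model A binary [risk_model()] with a `flag_key`.
#' @param models Model registry used to derive missing attributes before
#'   classification; defaults to a registry containing `model`.
#' @param registry A [unit_registry()].
#' @return An object of class `concordance_report`.
#' @export
concordance <- function(records, model, models = NULL,
                        registry = builtin_units()) {
  stopifnot(inherits(model, "risk_model"))
  if (is.null(model$flag_key)) {
    stop("model has no expert-flag key", call. = FALSE)
  }
  if (is.null(models)) {
    models <- stats::setNames(list(model), model$name)
  }
  expert <- numeric(0)
  auto <- numeric(0)
  ids <- character(0)
  for (rec in records) {
    ef <- rec$expert_flags[model$flag_key]
    if (is.null(rec$expert_flags) || is.na(ef)) next
    cls <- classify_with_lift(rec, model, models, registry)
    if (!identical(cls$outcome, "classified")) next
    expert <- c(expert, unname(ef))
    auto <- c(auto, cls$at_risk)
    ids <- c(ids, rec$record_id)
  }
  if (length(expert) == 0L) {
    stop("no record has both an expert flag and a classifiable value",
         call. = FALSE)
  }
  n1 <- sum(expert == 1)
  n0 <- sum(expert == 0)
  tp <- if (n1 > 0) 100 * sum(auto == 1 & expert == 1) / n1 else NA_real_
  fp <- if (n0 > 0) 100 * sum(auto == 1 & expert == 0) / n0 else NA_real_
  structure(
    list(model = model$name, flag_key = model$flag_key,
         n_expert_at_risk = n1, n_expert_not_at_risk = n0,
         tp_rate_percent = tp, fp_rate_percent = fp,
         discordant_ids = ids[auto != expert]),
    class = "concordance_report"
  )
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("<concordance> %s (%s): TP %s%%  FP %s%%  (n+ %d, n- %d, %d discordant)\n",
              x$model, x$flag_key,
              ifelse(is.na(x$tp_rate_percent), "NA",
                     format(round(x$tp_rate_percent, 1))),
              ifelse(is.na(x$fp_rate_percent), "NA",
                     format(round(x$fp_rate_percent, 1))),
              x$n_expert_at_risk, x$n_expert_not_at_risk,
              length(x$discordant_ids)))
  invisible(x)
}

#' Concordance table across the seven binary attributes
#'
#' @param records List of [patient_record()]s with expert flags.
#' @param models A model registry ([builtin_models()]).
#' @param registry A [unit_registry()].
#' @return A data.frame with one row per binary model (attribute,
#'   tp_rate_percent, fp_rate_percent, n_expert_at_risk,
#'   n_expert_not_at_risk, n_discordant).
#' @export
concordance_table <- function(records, models = builtin_models("modified"),
                              registry = builtin_units()) {
  keys <- binary_model_keys(models)
  rows <- lapply(keys, function(k) {
    rep_ <- concordance(records, models[[k]], models = models,
                        registry = registry)
    data.frame(attribute = rep_$flag_key,
               tp_rate_percent = rep_$tp_rate_percent,
               fp_rate_percent = rep_$fp_rate_percent,
               n_expert_at_risk = rep_$n_expert_at_risk,
               n_expert_not_at_risk = rep_$n_expert_not_at_risk,
               n_discordant = length(rep_$discordant_ids),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Recover a personal decision threshold from labeled values
#'
#' Finds the single inclusive-at-risk cutoff that maximizes concordance
#' with binary labels. On perfectly separable data the boundary is the
#' extreme observed value on the at-risk side of the gap (the smallest
#' at-risk value for `at_risk_if_ge`, the largest for `at_risk_if_le`) —
#' matching the convention of personalized guideline models that place
#' the threshold at an inclusive at-risk bound. On non-separable data the
#' boundary maximizes concordance, ties broken toward the smaller at-risk
#' set.
#'
#' @param values Numeric measurements (finite).
#' @param labels 0/1 expert labels, same length.
#' @param direction `"at_risk_if_ge"` or `"at_risk_if_le"`.
#' @return An object of class `threshold_fit`: `direction`, `boundary`,
#'   `gap_interval` (closest safe-side and risk-side observed values),
#'   `concordance_percent`, `separable`.
#' @export
recover_threshold <- function(values, labels,
                              direction = c("at_risk_if_ge",
                                            "at_risk_if_le")) {
  direction <- match.arg(direction)
  stopifnot(length(values) == length(labels), length(values) > 0)
  if (!all(is.finite(values))) stop("values must be finite", call. = FALSE)
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1", call. = FALSE)
  if (length(unique(labels)) < 2L) {
    stop("both labels must be present: no recoverable boundary",
         call. = FALSE)
  }
  ge <- identical(direction, "at_risk_if_ge")
  cand <- sort(unique(values))
  acc <- vapply(cand, function(b) {
    pred <- if (ge) as.numeric(values >= b) else as.numeric(values <= b)
    mean(pred == labels)
  }, numeric(1))
  best <- max(acc)
  winners <- cand[acc == best]
  # smaller at-risk set: larger cutoff for >=, smaller for <=
  boundary <- if (ge) max(winners) else min(winners)

  pred <- if (ge) values >= boundary else values <= boundary
  if (ge) {
    safe_side <- suppressWarnings(max(values[values < boundary]))
    risk_side <- min(values[values >= boundary])
    gap <- c(safe_side, risk_side)
  } else {
    safe_side <- suppressWarnings(min(values[values > boundary]))
    risk_side <- max(values[values <= boundary])
    gap <- c(risk_side, safe_side)
  }
  structure(
    list(direction = direction, boundary = boundary,
         gap_interval = gap, concordance_percent = 100 * best,
         separable = isTRUE(all.equal(best, 1))),
    class = "threshold_fit"
  )
}

#' @export
print.threshold_fit <- function(x, ...) {
  cat(sprintf("<threshold_fit> %s at %s (concordance %.1f%%%s)\n",
              x$direction, format(x$boundary), x$concordance_percent,
              if (x$separable) ", separable" else ""))
  invisible(x)
}

#' Write a model registry to a JSON config file
#'
#' Personalized guideline sets can be published and swapped; this is the
#' declarative on-disk form (name, class, unit, analyte, bands with
#' inclusivity flags, sex overrides).
#'
#' @param models A model registry (named list of [risk_model()]s).
#' @param path Output path; when NULL the config list is returned.
#' @export
write_model_set <- function(models, path = NULL) {
  ser_band <- function(b) {
    list(lower = if (is.finite(b$lower)) b$lower else "-Inf",
         upper = if (is.finite(b$upper)) b$upper else "Inf",
         lower_inclusive = b$lower_inclusive,
         upper_inclusive = b$upper_inclusive,
         label = b$label, at_risk = b$at_risk)
  }
  cfg <- list(set = attr(models, "set"),
              models = lapply(unname(models), function(m) {
                list(name = m$name, mclass = m$mclass,
                     canonical_unit = m$canonical_unit,
                     analyte = m$analyte, flag_key = m$flag_key,
                     bands = lapply(m$bands, ser_band),
                     sex_overrides = if (is.null(m$sex_overrides)) NULL else
                       lapply(m$sex_overrides,
                              function(bs) lapply(bs, ser_band)))
              }))
  if (!is.null(path)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
    return(invisible(cfg))
  }
  cfg
}

#' Read a model registry from a JSON config file
#'
#' @param config Path to JSON written by [write_model_set()], or the
#'   config list itself.
#' @return A named model registry.
#' @export
read_model_set <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config)
  de_band <- function(b) {
    num <- function(x) if (is.character(x)) as.numeric(x) else x
    band(num(b$lower), num(b$upper), b$label, b$at_risk,
         lower_inclusive = isTRUE(b$lower_inclusive),
         upper_inclusive = isTRUE(b$upper_inclusive))
  }
  models <- lapply(config$models, function(m) {
    risk_model(m$name, m$mclass, m$canonical_unit,
               bands = lapply(m$bands, de_band),
               analyte = m$analyte,
               sex_overrides = if (is.null(m$sex_overrides)) NULL else
                 lapply(m$sex_overrides,
                        function(bs) lapply(bs, de_band)),
               flag_key = m$flag_key)
  })
  names(models) <- vapply(models, `[[`, character(1), "name")
  attr(models, "set") <- config$set
  models
}
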
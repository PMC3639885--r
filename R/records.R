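#' Measurement classes of the clinical record model
#'
#' Grounding classes are tied directly to observed data; derived classes
#' (LDL cholesterol, body mass index, the Framingham general-CVD score)
#' are computed from them by the derivation services.
#'
#' @return A data.frame with columns `name` and `grounding`.
#' @export
measurement_classes <- function() {
  data.frame(
    name = c("Age", "Sex", "Mass", "Height",
             "SystolicBloodPressure", "DiastolicBloodPressure",
             "BloodSugarConcentration",
             "SerumCholesterolConcentration",
             "SerumHDLCholesterolConcentration",
             "SerumTriglycerideConcentration",
             "SerumLDLCholesterolConcentration",
             "BodyMassIndex",
             "GeneralCVDFraminghamRiskScore"),
    grounding = c(rep(TRUE, 10), FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

# analyte tag used for concentration bridging, per measurement class
class_analyte <- function(mclass) {
  switch(mclass,
         SerumCholesterolConcentration = "total-cholesterol",
         SerumHDLCholesterolConcentration = "hdl",
         SerumLDLCholesterolConcentration = "ldl",
         SerumTriglycerideConcentration = "triglyceride",
         BloodSugarConcentration = "glucose",
         NULL)
}

#' Construct a patient record
#'
#' One record per encounter: a set of measurement attributes (at most one
#' per measurement class), optional expert binary flags per attribute,
#' an optional expert ternary overall risk (1 low / 2 moderate / 3 high),
#' and optional smoking / diabetes / blood-pressure-treatment status.
#'
#' @param record_id Identifier.
#' @param attributes Named list (by measurement class) of attributes as
#'   created by [set_attribute()]; usually left empty and filled via
#'   [set_attribute()] / [set_sex()].
#' @param expert_flags Named 0/1 vector over
#'   `c("SBP","DBP","CHOL","HDL","TG","BMI","LDL")` (any subset).
#' @param expert_ternary Integer in 1:3, or NULL.
#' @param smoker,diabetic,bp_treated Logical or NULL when unknown.
#' @return An object of class `patient_record`.
#' @export
patient_record <- function(record_id, attributes = list(),
                           expert_flags = NULL, expert_ternary = NULL,
                           smoker = NULL, diabetic = NULL,
                           bp_treated = NULL) {
  if (!is.null(expert_ternary)) {
    expert_ternary <- as.integer(expert_ternary)
    if (!expert_ternary %in% 1:3) {
      stop("expert_ternary must be 1, 2 or 3", call. = FALSE)
    }
  }
  if (!is.null(expert_flags)) {
    if (!all(expert_flags %in% c(0, 1))) {
      stop("expert flags must be 0/1", call. = FALSE)
    }
  }
  structure(
    list(record_id = as.character(record_id), attributes = attributes,
         expert_flags = expert_flags, expert_ternary = expert_ternary,
         smoker = smoker, diabetic = diabetic, bp_treated = bp_treated),
    class = "patient_record"
  )
}

#' @export
print.patient_record <- function(x, ...) {
  cat("<patient_record> ", x$record_id, "\n", sep = "")
  for (a in x$attributes) {
    if (identical(a$mclass, "Sex")) {
      cat("  Sex: ", a$sex, "\n", sep = "")
    } else {
      cat("  ", a$mclass, ": ", format(a$quantity$value), " ",
          a$quantity$unit, "\n", sep = "")
    }
  }
  if (!is.null(x$expert_flags)) {
    cat("  expert flags:",
        paste(names(x$expert_flags), x$expert_flags, sep = "=",
              collapse = " "), "\n")
  }
  if (!is.null(x$expert_ternary)) {
    cat("  expert ternary:", x$expert_ternary, "\n")
  }
  invisible(x)
}

#' Attach a measurement attribute to a record
#'
#' @param record A [patient_record()].
#' @param mclass Measurement class name (see [measurement_classes()]);
#'   not `"Sex"` (use [set_sex()]).
#' @param q A [quantity()].
#' @return The updated record.
#' @export
set_attribute <- function(record, mclass, q) {
  stopifnot(inherits(record, "patient_record"), inherits(q, "quantity"))
  if (!mclass %in% measurement_classes()$name || identical(mclass, "Sex")) {
    stop("unknown measurement class: ", mclass, call. = FALSE)
  }
  record$attributes[[mclass]] <- list(mclass = mclass, quantity = q)
  record
}

#' Attach the sex attribute to a record
#'
#' Sex is categorical, not a quantity.
#'
#' @param record A [patient_record()].
#' @param sex `"male"` or `"female"`.
#' @return The updated record.
#' @export
set_sex <- function(record, sex) {
  if (!sex %in% c("male", "female")) {
    stop("sex must be 'male' or 'female'", call. = FALSE)
  }
  record$attributes[["Sex"]] <- list(mclass = "Sex", sex = sex)
  record
}

#' Sex of a record, or NULL
#' @param record A [patient_record()].
#' @export
get_sex <- function(record) {
  a <- record$attributes[["Sex"]]
  if (is.null(a)) NULL else a$sex
}

#' Retrieve (and optionally convert) a record's measurement
#'
#' @param record A [patient_record()].
#' @param mclass Measurement class name.
#' @param target_unit Optional unit to convert to.
#' @param analyte Analyte tag for concentration bridging; defaults to the
#'   class's own analyte (e.g. HDL measurements bridge with the HDL rule).
#' @param registry A [unit_registry()].
#' @return A [quantity()], or `NULL` when the attribute is absent.
#' @export
get_quantity <- function(record, mclass, target_unit = NULL, analyte = NULL,
                         registry = builtin_units()) {
  a <- record$attributes[[mclass]]
  if (is.null(a) || identical(mclass, "Sex")) return(NULL)
  q <- a$quantity
  if (is.null(target_unit)) return(q)
  if (is.null(analyte)) analyte <- class_analyte(mclass)
  convert_quantity(q, target_unit, analyte = analyte, registry = registry)
}

#' Shipped legacy-table column mapping
#'
#' Maps the legacy spreadsheet headers to measurement classes, the `*_GR`
#' binary expert-flag columns to their attribute keys, `RISK GR` to the
#' ternary label, and optional `SMOKER` / `DIABETIC` / `BPTREATED`
#' columns to record status fields.
#'
#' @return A list with elements `measurements`, `flags`, `ternary`,
#'   `status`, `id`.
#' @export
default_column_map <- function() {
  list(
    measurements = c(
      SBP = "SystolicBloodPressure",
      DBP = "DiastolicBloodPressure",
      TOTALCHOL = "SerumCholesterolConcentration",
      HDL = "SerumHDLCholesterolConcentration",
      TG = "SerumTriglycerideConcentration",
      LDL = "SerumLDLCholesterolConcentration",
      GLUCOSE = "BloodSugarConcentration",
      AGE = "Age",
      HEIGHT = "Height",
      WEIGHT = "Mass",
      BMI = "BodyMassIndex"
    ),
    gender = "GENDER",
    flags = c("TG GR" = "TG", "HDL GR" = "HDL", "LDL GR" = "LDL",
              "CHOL GR" = "CHOL", "BMI GR" = "BMI", "DBP GR" = "DBP",
              "SBP GR" = "SBP"),
    ternary = "RISK GR",
    status = c(SMOKER = "smoker", DIABETIC = "diabetic",
               BPTREATED = "bp_treated"),
    id = "ID"
  )
}

#' Shipped unit assumptions for the legacy table
#'
#' Height in meters, weight in kilograms, blood pressures in mmHg, lipid
#' and glucose concentrations in mg/dl, age in years, BMI in kg/m2.
#'
#' @return Named character vector MeasurementClass -> unit name.
#' @export
default_unit_assumptions <- function() {
  c(Age = "year",
    Height = "meter",
    Mass = "kilogram",
    SystolicBloodPressure = "millimeter-of-mercury-column",
    DiastolicBloodPressure = "millimeter-of-mercury-column",
    BloodSugarConcentration = "milligram-per-deciliter",
    SerumCholesterolConcentration = "milligram-per-deciliter",
    SerumHDLCholesterolConcentration = "milligram-per-deciliter",
    SerumTriglycerideConcentration = "milligram-per-deciliter",
    SerumLDLCholesterolConcentration = "milligram-per-deciliter",
    BodyMassIndex = "kilogram-per-meter-squared")
}

#' Read patient records from a legacy spreadsheet-style table
#'
#' Comma- or tab-separated text with a header row (dialect auto-detected).
#' Numeric cells become measurement attributes with units attached from
#' `unit_assumptions`; `*_GR` columns become expert flags; `RISK GR`
#' becomes the ternary label. Missing cells parse to absent attributes.
#'
#' @param input Path to a file, or a character vector of lines, or a
#'   single string containing the table text.
#' @param column_map As [default_column_map()].
#' @param unit_assumptions As [default_unit_assumptions()].
#' @param registry A [unit_registry()].
#' @return List of [patient_record()]s (one per row).
#' @export
read_legacy_table <- function(input, column_map = default_column_map(),
                              unit_assumptions = default_unit_assumptions(),
                              registry = builtin_units()) {
  txt <- if (length(input) == 1L && !grepl("\n", input, fixed = TRUE) &&
             file.exists(input)) {
    readLines(input, warn = FALSE)
  } else {
    unlist(strsplit(paste(input, collapse = "\n"), "\n", fixed = TRUE))
  }
  txt <- txt[nzchar(trimws(txt))]
  if (length(txt) == 0L) return(list())
  sep <- if (grepl("\t", txt[[1]], fixed = TRUE)) "\t" else ","
  df <- utils::read.csv(text = paste(txt, collapse = "\n"), sep = sep,
                        check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (nrow(df) == 0L) return(list())

  headers <- names(df)
  known <- c(names(column_map$measurements), column_map$gender,
             names(column_map$flags), column_map$ternary,
             names(column_map$status), column_map$id)
  unknown <- setdiff(headers, known)
  if (length(unknown) > 0L) {
    stop("unmapped header(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }

  parse_num <- function(cell, header, i) {
    if (is.na(cell) || !nzchar(trimws(cell))) return(NA_real_)
    v <- suppressWarnings(as.numeric(cell))
    if (is.na(v)) {
      stop(sprintf("row %d: unparseable numeric '%s' in column %s",
                   i, cell, header), call. = FALSE)
    }
    v
  }

  records <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    id <- if (!is.null(column_map$id) && column_map$id %in% headers) {
      df[i, column_map$id]
    } else {
      paste0("row", i)
    }
    rec <- patient_record(id)
    for (h in intersect(names(column_map$measurements), headers)) {
      v <- parse_num(df[i, h], h, i)
      if (is.na(v)) next
      mclass <- column_map$measurements[[h]]
      unit <- unit_assumptions[[mclass]]
      if (is.null(unit) || is.na(unit)) {
        stop("no unit assumption for class ", mclass, call. = FALSE)
      }
      rec <- set_attribute(rec, mclass, quantity(v, unit))
    }
    if (!is.null(column_map$gender) && column_map$gender %in% headers) {
      g <- trimws(df[i, column_map$gender])
      if (nzchar(g) && !is.na(g)) {
        sex <- switch(toupper(g), M = , MALE = "male",
                      F = , FEMALE = "female", NA_character_)
        if (is.na(sex)) {
          stop(sprintf("row %d: unknown gender code '%s'", i, g),
               call. = FALSE)
        }
        rec <- set_sex(rec, sex)
      }
    }
    flags <- numeric(0)
    for (h in intersect(names(column_map$flags), headers)) {
      v <- parse_num(df[i, h], h, i)
      if (is.na(v)) next
      if (!v %in% c(0, 1)) {
        stop(sprintf("row %d: flag column %s must be 0/1, got %s", i, h,
                     format(v)), call. = FALSE)
      }
      flags[[column_map$flags[[h]]]] <- v
    }
    if (length(flags) > 0L) rec$expert_flags <- flags
    if (!is.null(column_map$ternary) && column_map$ternary %in% headers) {
      v <- parse_num(df[i, column_map$ternary], column_map$ternary, i)
      if (!is.na(v)) {
        if (!v %in% 1:3) {
          stop(sprintf("row %d: ternary risk must be 1, 2 or 3", i),
               call. = FALSE)
        }
        rec$expert_ternary <- as.integer(v)
      }
    }
    for (h in intersect(names(column_map$status), headers)) {
      cell <- trimws(df[i, h])
      if (!nzchar(cell) || is.na(cell)) next
      val <- switch(toupper(cell),
                    "1" = , "TRUE" = , "YES" = , "Y" = TRUE,
                    "0" = , "FALSE" = , "NO" = , "N" = FALSE,
                    stop(sprintf("row %d: bad status '%s' in %s", i, cell,
                                 h), call. = FALSE))
      rec[[column_map$status[[h]]]] <- val
    }
    records[[i]] <- rec
  }
  records
}

#' Write patient records as a legacy-dialect CSV
#'
#' Emits the shipped header set (Table-2 style) plus SMOKER/DIABETIC/
#' BPTREATED status columns when any record carries them.
#'
#' @param records List of [patient_record()]s.
#' @param path Optional output path; when NULL the CSV text is returned.
#' @param registry A [unit_registry()].
#' @return CSV text (character vector of lines), invisibly when written.
#' @export
write_legacy_table <- function(records, path = NULL,
                               registry = builtin_units()) {
  cmap <- default_column_map()
  assume <- default_unit_assumptions()
  meas_headers <- setdiff(names(cmap$measurements), c("LDL", "BMI", "GLUCOSE"))
  has_glucose <- any(vapply(records, function(r) {
    !is.null(r$attributes[["BloodSugarConcentration"]])
  }, logical(1)))
  if (has_glucose) meas_headers <- c(meas_headers, "GLUCOSE")
  has_status <- vapply(c("smoker", "diabetic", "bp_treated"), function(f) {
    any(vapply(records, function(r) !is.null(r[[f]]), logical(1)))
  }, logical(1))
  status_headers <- names(cmap$status)[match(
    c("smoker", "diabetic", "bp_treated")[has_status], cmap$status)]
  headers <- c("ID", meas_headers, cmap$gender, status_headers,
               names(cmap$flags), cmap$ternary)

  fmt <- function(x) {
    if (is.null(x) || (length(x) == 1 && is.na(x))) "" else
      format(x, digits = 15, scientific = FALSE, trim = TRUE)
  }
  rows <- vapply(records, function(r) {
    cells <- character(length(headers))
    names(cells) <- headers
    cells[["ID"]] <- r$record_id
    for (h in meas_headers) {
      mclass <- cmap$measurements[[h]]
      q <- get_quantity(r, mclass, target_unit = assume[[mclass]],
                        registry = registry)
      cells[[h]] <- if (is.null(q)) "" else fmt(q$value)
    }
    sx <- get_sex(r)
    cells[[cmap$gender]] <- if (is.null(sx)) "" else
      if (identical(sx, "male")) "M" else "F"
    for (h in status_headers) {
      v <- r[[cmap$status[[h]]]]
      cells[[h]] <- if (is.null(v)) "" else if (isTRUE(v)) "1" else "0"
    }
    for (h in names(cmap$flags)) {
      key <- cmap$flags[[h]]
      v <- if (is.null(r$expert_flags)) NULL else r$expert_flags[key]
      cells[[h]] <- if (is.null(v) || is.na(v)) "" else fmt(unname(v))
    }
    cells[[cmap$ternary]] <- fmt(r$expert_ternary)
    paste(cells, collapse = ",")
  }, character(1))
  out <- c(paste(headers, collapse = ","), rows)
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}
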
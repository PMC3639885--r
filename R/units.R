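#' Create an empty unit registry
#'
#' A unit registry holds compositional unit definitions (base units,
#' prefixed/dimensioned simple derivations, multi-component complex
#' derivations), a case-insensitive alias table, and analyte-specific
#' bridging rules between mass and molar concentrations.
#'
#' @return An object of class `unit_registry`.
#' @seealso [builtin_units()] for the shipped clinical registry.
#' @export
unit_registry <- function() {
  reg <- new.env(parent = emptyenv())
  reg$units <- list()     # canonical name -> cardio_unit
  reg$aliases <- list()   # lowercase alias -> canonical name
  reg$bridges <- list()   # analyte -> mg/dl per mmol/L factor
  class(reg) <- "unit_registry"
  reg
}

#' @export
print.unit_registry <- function(x, ...) {
  cat("<unit_registry> ", length(x$units), " units, ",
      length(x$bridges), " analyte bridges\n", sep = "")
  invisible(x)
}

new_unit <- function(name, kind, derives_from, prefix_factor, quality,
                     dims, scale) {
  structure(
    list(name = name, kind = kind, derives_from = derives_from,
         prefix_factor = prefix_factor, quality = quality,
         dims = dims, scale = scale),
    class = "cardio_unit"
  )
}

#' @export
print.cardio_unit <- function(x, ...) {
  cat("<unit> ", x$name, " [", x$kind, ", ", x$quality, "]\n", sep = "")
  invisible(x)
}

register_unit <- function(registry, unit, aliases = character()) {
  registry$units[[unit$name]] <- unit
  for (a in unique(c(unit$name, aliases))) {
    registry$aliases[[tolower(a)]] <- unit$name
  }
  unit
}

# Resolve a unit by object, canonical name, or alias. NULL if absent.
resolve_unit <- function(registry, unit) {
  if (inherits(unit, "cardio_unit")) {
    return(registry$units[[unit$name]])
  }
  stopifnot(is.character(unit), length(unit) == 1L)
  canon <- registry$aliases[[tolower(unit)]]
  if (is.null(canon)) NULL else registry$units[[canon]]
}

#' Look up a unit in a registry
#'
#' @param registry A [unit_registry()].
#' @param name Unit name or alias (case-insensitive).
#' @return The unit, or `NULL` when no such unit is registered (no unit is
#'   ever fabricated for an unknown name).
#' @export
unit_lookup <- function(registry, name) resolve_unit(registry, name)

# Normalize a dimension vector: drop zero exponents, sort by base name.
norm_dims <- function(dims) {
  storage.mode(dims) <- "double"
  dims <- dims[dims != 0]
  dims[order(names(dims))]
}

# Physical-quality tag inferred from the base-quality signature.
infer_quality <- function(registry, dims) {
  if (length(dims) == 0L) return("dimensionless")
  quals <- vapply(names(dims), function(nm) registry$units[[nm]]$quality,
                  character(1))
  sig <- paste(sort(paste0(quals, "^", dims)), collapse = " ")
  known <- c(
    "mass^1" = "mass",
    "length^1" = "length",
    "volume^1" = "volume",
    "pressure^1" = "pressure",
    "amount^1" = "amount",
    "time^1" = "time",
    "length^2" = "area",
    "length^-2 mass^1" = "area-density",
    "mass^1 volume^-1" = "mass-concentration",
    "amount^1 volume^-1" = "molar-concentration"
  )
  if (!is.null(known[[sig]]) && !is.na(known[[sig]])) known[[sig]] else "composite"
}

#' Register a base unit
#'
#' Base units derive from nothing, carry prefix factor 1 and define a
#' physical quality (mass, length, volume, pressure, amount, time, or
#' dimensionless).
#'
#' @param registry A [unit_registry()].
#' @param name Canonical unit name.
#' @param quality Physical-quality tag.
#' @param aliases Optional extra (case-insensitive) lookup names.
#' @return The registered unit, invisibly usable wherever a unit is expected.
#' @export
make_base_unit <- function(registry, name, quality, aliases = character()) {
  existing <- registry$units[[name]]
  if (!is.null(existing)) return(existing)
  dims <- if (identical(quality, "dimensionless")) {
    stats::setNames(numeric(0), character(0))
  } else {
    stats::setNames(1.0, name)
  }
  u <- new_unit(name, "base", list(), 1.0, quality, dims, 1.0)
  register_unit(registry, u, aliases)
}

#' Derive a simple (prefixed and/or dimensioned) unit from one base unit
#'
#' A simple derived unit scales exactly one base unit by a prefix factor
#' and raises it to an integer dimensional size, e.g. millimeter
#' (meter, 0.001, 1) or meter-squared (meter, 1, 2). Registering the same
#' (base, prefix, exponent) triple twice returns the identical unit.
#'
#' @param registry A [unit_registry()].
#' @param name Canonical name for the new unit.
#' @param base The base unit (name or unit object); must be of kind "base".
#' @param prefix_factor Positive decimal scale relative to the base.
#' @param exponent Nonzero integer dimensional size.
#' @param aliases Optional extra lookup names.
#' @return The derived unit.
#' @export
make_simple_derived <- function(registry, name, base, prefix_factor = 1.0,
                                exponent = 1L, aliases = character()) {
  b <- resolve_unit(registry, base)
  if (is.null(b)) stop("unknown base unit", call. = FALSE)
  if (!identical(b$kind, "base")) {
    stop("simple derived units must derive from a base unit", call. = FALSE)
  }
  if (!is.numeric(prefix_factor) || prefix_factor <= 0) {
    stop("prefix_factor must be positive", call. = FALSE)
  }
  exponent <- as.integer(exponent)
  if (exponent == 0L) stop("exponent must be nonzero", call. = FALSE)

  # idempotency on the defining triple
  for (u in registry$units) {
    if (identical(u$kind, "simple_derived") &&
        identical(u$derives_from[[1]]$unit, b$name) &&
        isTRUE(all.equal(u$prefix_factor, prefix_factor)) &&
        identical(u$derives_from[[1]]$exponent, exponent)) {
      return(u)
    }
  }
  dims <- norm_dims(stats::setNames(as.numeric(exponent), b$name))
  scale <- prefix_factor^exponent
  u <- new_unit(name, "simple_derived",
                list(list(unit = b$name, exponent = exponent)),
                prefix_factor, infer_quality(registry, dims), dims, scale)
  register_unit(registry, u, aliases)
}

#' Derive a complex unit from two or more components
#'
#' Components are (unit, exponent) pairs; the resulting unit's scale and
#' dimensions are the products of its components', order-insensitively.
#' E.g. kilogram-per-meter-squared from (kilogram, 1), (meter, -2).
#'
#' @param registry A [unit_registry()].
#' @param name Canonical name.
#' @param components List of `list(unit =, exponent =)` pairs (at least 2).
#' @param aliases Optional extra lookup names.
#' @return The derived unit.
#' @export
make_complex_derived <- function(registry, name, components,
                                 aliases = character()) {
  if (length(components) < 2L) {
    stop("a complex derived unit needs at least 2 components", call. = FALSE)
  }
  dims <- stats::setNames(numeric(0), character(0))
  scale <- 1.0
  parts <- list()
  for (comp in components) {
    u <- resolve_unit(registry, comp$unit)
    if (is.null(u)) stop("unknown component unit", call. = FALSE)
    e <- comp$exponent
    add <- u$dims * e
    for (b in names(add)) {
      prev <- if (b %in% names(dims)) dims[[b]] else 0
      dims[b] <- prev + add[[b]]
    }
    scale <- scale * u$scale^e
    parts[[length(parts) + 1L]] <- list(unit = u$name, exponent = e)
  }
  dims <- norm_dims(dims)
  ord <- order(vapply(parts, `[[`, character(1), "unit"))
  parts <- parts[ord]
  u <- new_unit(name, "complex_derived", parts, 1.0,
                infer_quality(registry, dims), dims, scale)
  register_unit(registry, u, aliases)
}

#' Register an analyte bridge between mass and molar concentration
#'
#' The factor is expressed in the clinical convention: mg/dl per mmol/L
#' (e.g. 38.67 for cholesterol species, i.e. mmol/L = (mg/dl) / 38.67).
#'
#' @param registry A [unit_registry()].
#' @param analyte Analyte tag (e.g. "total-cholesterol", "triglyceride").
#' @param mgdl_per_mmol Positive conversion factor.
#' @export
register_bridge <- function(registry, analyte, mgdl_per_mmol) {
  stopifnot(is.numeric(mgdl_per_mmol), mgdl_per_mmol > 0)
  registry$bridges[[analyte]] <- mgdl_per_mmol
  invisible(registry)
}

#' A numeric value bound to a unit of measure
#'
#' @param value Finite numeric scalar.
#' @param unit Unit name (resolved against a registry at use time) or a
#'   unit object.
#' @return An object of class `quantity`.
#' @export
quantity <- function(value, unit) {
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value)) {
    stop("quantity value must be a finite numeric scalar", call. = FALSE)
  }
  nm <- if (inherits(unit, "cardio_unit")) unit$name else as.character(unit)
  structure(list(value = as.numeric(value), unit = nm), class = "quantity")
}

#' @export
print.quantity <- function(x, ...) {
  cat(format(x$value), " ", x$unit, "\n", sep = "")
  invisible(x)
}

#' @export
format.quantity <- function(x, ...) paste(format(x$value, ...), x$unit)

# mg/dl and mmol/L reference scales used when bridging concentrations.
.MGDL_SCALE <- 0.01    # g/L per mg/dl
.MMOLL_SCALE <- 0.001  # mol/L per mmol/L

#' Convert a quantity to a target unit
#'
#' Conversion composes the registered prefix/dimension factors. Two units
#' are compatible when their physical qualities (dimension signatures)
#' match; additionally mass-concentration and molar-concentration are
#' bridged through an analyte-specific molar-mass rule, in which case the
#' `analyte` must be given.
#'
#' @param q A [quantity()].
#' @param target Target unit (name or unit object).
#' @param analyte Analyte tag, required only when bridging mass and molar
#'   concentration ("total-cholesterol", "hdl", "ldl", "triglyceride",
#'   "glucose").
#' @param registry A [unit_registry()]; defaults to [builtin_units()].
#' @return A [quantity()] in the target unit.
#' @export
convert_quantity <- function(q, target, analyte = NULL,
                             registry = builtin_units()) {
  stopifnot(inherits(q, "quantity"))
  from <- resolve_unit(registry, q$unit)
  to <- resolve_unit(registry, target)
  if (is.null(from)) stop("unknown unit: ", q$unit, call. = FALSE)
  if (is.null(to)) stop("unknown target unit", call. = FALSE)

  if (identical(from$dims, to$dims)) {
    return(quantity(q$value * from$scale / to$scale, to))
  }

  quals <- c(from$quality, to$quality)
  if (setequal(quals, c("mass-concentration", "molar-concentration"))) {
    if (is.null(analyte)) {
      stop("analyte required to bridge mass and molar concentration",
           call. = FALSE)
    }
    d <- registry$bridges[[analyte]]
    if (is.null(d)) {
      stop("no bridging rule registered for analyte '", analyte, "'",
           call. = FALSE)
    }
    if (identical(from$quality, "mass-concentration")) {
      mgdl <- q$value * from$scale / .MGDL_SCALE
      mmol <- mgdl / d
      return(quantity(mmol * .MMOLL_SCALE / to$scale, to))
    } else {
      mmol <- q$value * from$scale / .MMOLL_SCALE
      mgdl <- mmol * d
      return(quantity(mgdl * .MGDL_SCALE / to$scale, to))
    }
  }
  stop("units '", from$name, "' and '", to$name,
       "' are not conversion-compatible (", from$quality, " vs ",
       to$quality, ")", call. = FALSE)
}

.cardiolift <- new.env(parent = emptyenv())

#' The shipped clinical unit registry
#'
#' Builds (once per session) the registry of units used by the clinical
#' record model: bases gram, meter, liter, pascal, mole, year; prefixed
#' derivations including kilogram (gram is the base mass unit, kilogram a
#' prefixed derivation), millimeter, deciliter, millimole, kilopascal and
#' millimeter-of-mercury-column (133.322 Pa); the dimensioned
#' meter-squared; and the complex kilogram-per-meter-squared,
#' milligram-per-deciliter and milli-mole-per-liter. Analyte bridges:
#' cholesterol species 38.67, triglyceride 88.57, glucose 18.016 (mg/dl
#' per mmol/L).
#'
#' @return A [unit_registry()] (memoized; idempotent).
#' @export
builtin_units <- function() {
  if (!is.null(.cardiolift$registry)) return(.cardiolift$registry)
  reg <- unit_registry()

  make_base_unit(reg, "gram", "mass", aliases = "g")
  make_base_unit(reg, "meter", "length", aliases = c("m", "metre"))
  make_base_unit(reg, "liter", "volume", aliases = c("l", "litre"))
  make_base_unit(reg, "pascal", "pressure", aliases = "Pa")
  make_base_unit(reg, "mole", "amount", aliases = "mol")
  make_base_unit(reg, "year", "time", aliases = c("y", "yr", "years"))
  make_base_unit(reg, "dimensionless", "dimensionless",
                 aliases = c("unitless", "point", "points"))

  make_simple_derived(reg, "kilogram", "gram", 1000, 1L, aliases = "kg")
  make_simple_derived(reg, "milligram", "gram", 1e-3, 1L, aliases = "mg")
  make_simple_derived(reg, "millimeter", "meter", 1e-3, 1L, aliases = "mm")
  make_simple_derived(reg, "centimeter", "meter", 1e-2, 1L, aliases = "cm")
  make_simple_derived(reg, "deciliter", "liter", 0.1, 1L,
                      aliases = c("dl", "deci-liter"))
  make_simple_derived(reg, "millimole", "mole", 1e-3, 1L,
                      aliases = c("mmol", "milli-mole"))
  make_simple_derived(reg, "kilopascal", "pascal", 1000, 1L, aliases = "kPa")
  # 1 mmHg = 133.322 Pa; reproduces the AHA dual-unit pressure tables.
  make_simple_derived(reg, "millimeter-of-mercury-column", "pascal",
                      133.322, 1L,
                      aliases = c("mmHg", "mm Hg",
                                  "milli-meter-of-mercury-column",
                                  "millimeter-of mercury-column"))
  make_simple_derived(reg, "meter-squared", "meter", 1.0, 2L,
                      aliases = c("m2", "m^2", "square-meter"))

  make_complex_derived(reg, "kilogram-per-meter-squared",
                       list(list(unit = "kilogram", exponent = 1L),
                            list(unit = "meter", exponent = -2L)),
                       aliases = c("kg/m2", "kg/m^2",
                                   "kilogram-per-meter-square"))
  make_complex_derived(reg, "milligram-per-deciliter",
                       list(list(unit = "milligram", exponent = 1L),
                            list(unit = "deciliter", exponent = -1L)),
                       aliases = c("mg/dl", "mg/dL",
                                   "milli-gram-per-deci-liter"))
  make_complex_derived(reg, "milli-mole-per-liter",
                       list(list(unit = "millimole", exponent = 1L),
                            list(unit = "liter", exponent = -1L)),
                       aliases = c("mmol/l", "mmol/L", "millimole-per-liter",
                                   "mili-mole-per-liter"))
  make_complex_derived(reg, "gram-per-liter",
                       list(list(unit = "gram", exponent = 1L),
                            list(unit = "liter", exponent = -1L)),
                       aliases = "g/l")

  register_bridge(reg, "total-cholesterol", 38.67)
  register_bridge(reg, "hdl", 38.67)
  register_bridge(reg, "ldl", 38.67)
  register_bridge(reg, "triglyceride", 88.57)
  register_bridge(reg, "glucose", 18.016)

  .cardiolift$registry <- reg
  reg
}

#' Serialize a unit registry to a config list / JSON file
#'
#' @param registry A [unit_registry()].
#' @param path Optional file path; when given, JSON is written there.
#' @return The config list, invisibly when `path` is given.
#' @export
write_unit_registry <- function(registry, path = NULL) {
  cfg <- list(
    units = lapply(unname(registry$units), function(u) {
      list(name = u$name, kind = u$kind,
           derives_from = u$derives_from,
           prefix_factor = u$prefix_factor,
           quality = u$quality)
    }),
    aliases = registry$aliases,
    bridges = registry$bridges
  )
  if (!is.null(path)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
    return(invisible(cfg))
  }
  cfg
}

#' Rebuild a unit registry from a config list / JSON file
#'
#' @param config A config list as produced by [write_unit_registry()], or
#'   a path to its JSON serialization.
#' @return A [unit_registry()].
#' @export
read_unit_registry <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config)
  reg <- unit_registry()
  pending <- config$units
  # bases first, then derivations in dependency order
  while (length(pending) > 0L) {
    placed <- FALSE
    keep <- list()
    for (u in pending) {
      deps <- vapply(u$derives_from, `[[`, character(1), "unit")
      if (identical(u$kind, "base")) {
        make_base_unit(reg, u$name, u$quality)
        placed <- TRUE
      } else if (all(deps %in% names(reg$units))) {
        if (identical(u$kind, "simple_derived")) {
          make_simple_derived(reg, u$name, deps[[1]], u$prefix_factor,
                              u$derives_from[[1]]$exponent)
        } else {
          comps <- lapply(u$derives_from, function(d) {
            list(unit = d$unit, exponent = d$exponent)
          })
          make_complex_derived(reg, u$name, comps)
        }
        placed <- TRUE
      } else {
        keep[[length(keep) + 1L]] <- u
      }
    }
    if (!placed) stop("unresolvable unit dependencies in config", call. = FALSE)
    pending <- keep
  }
  for (a in names(config$aliases)) reg$aliases[[a]] <- config$aliases[[a]]
  for (b in names(config$bridges)) {
    register_bridge(reg, b, config$bridges[[b]])
  }
  reg
}

#' Export unit definitions as Turtle
#'
#' Mirrors the compositional unit pattern: base units, simple derivations
#' carrying `muo:derivesFrom` plus a prefix/dimensionalSize, complex
#' derivations with one `muo:derivesFrom` per component.
#'
#' @param registry A [unit_registry()].
#' @return A single Turtle string.
#' @export
units_turtle <- function(registry) {
  lines <- c("@prefix muo: <http://example.org/muo#> .",
             "@prefix cardio: <http://example.org/cardio#> .",
             "@prefix xsd: <http://www.w3.org/2001/XMLSchema#> .",
             "")
  for (u in registry$units) {
    subj <- paste0("cardio:", u$name)
    type <- switch(u$kind,
                   base = "muo:BaseUnit",
                   simple_derived = "muo:SimpleDerivedUnit",
                   complex_derived = "muo:ComplexDerivedUnit")
    lines <- c(lines, paste0(subj, " a ", type, " ."))
    for (d in u$derives_from) {
      lines <- c(lines,
                 paste0(subj, " muo:derivesFrom cardio:", d$unit, " ."))
      if (identical(u$kind, "simple_derived") && d$exponent != 1L) {
        lines <- c(lines, paste0(subj, " muo:dimensionalSize \"",
                                 d$exponent, "\"^^xsd:float ."))
      }
    }
    if (identical(u$kind, "simple_derived") && u$prefix_factor != 1) {
      lines <- c(lines, paste0(subj, " muo:prefixFactor \"",
                               format(u$prefix_factor, digits = 15),
                               "\"^^xsd:double ."))
    }
  }
  paste(c(lines, ""), collapse = "\n")
}
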
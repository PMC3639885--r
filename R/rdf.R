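# Turtle serialization of the record schema: a PatientRecord node linked
# by sio:hasAttribute to attribute nodes, each linked by sio:hasMeasurement
# to a measurement node carrying sio:hasUnit and sio:hasValue. The writer
# emits one triple per line (an N-Triples-shaped Turtle profile) so the
# reader can stay simple while round-tripping losslessly.

.RDF_PREFIXES <- c(
  cardio = "http://example.org/cardio#",
  sio = "http://example.org/sio#",
  muo = "http://example.org/muo#",
  rdf = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
  xsd = "http://www.w3.org/2001/XMLSchema#"
)

fmt_double <- function(x) sprintf("\"%.17g\"^^xsd:double", x)

#' Serialize patient records to Turtle
#'
#' @param records List of [patient_record()]s.
#' @param prefixes Named character vector of namespace IRIs (the shipped
#'   dummy IRIs are configurable).
#' @return A single Turtle string; [read_rdf()] is its inverse.
#' @export
write_rdf <- function(records, prefixes = .RDF_PREFIXES) {
  lines <- sprintf("@prefix %s: <%s> .", names(prefixes), prefixes)
  n <- 0L
  for (rec in records) {
    n <- n + 1L
    rnode <- sprintf("cardio:rec%d", n)
    emit <- function(s, p, o) {
      lines[[length(lines) + 1L]] <<- paste(s, p, o, ".")
    }
    emit(rnode, "rdf:type", "cardio:PatientRecord")
    emit(rnode, "cardio:recordID",
         sprintf("\"%s\"^^xsd:string", rec$record_id))
    for (a in rec$attributes) {
      anode <- sprintf("%s_attr_%s", rnode, a$mclass)
      emit(rnode, "sio:hasAttribute", anode)
      emit(anode, "rdf:type", sprintf("cardio:%s", a$mclass))
      if (identical(a$mclass, "Sex")) {
        emit(anode, "cardio:hasSexValue",
             sprintf("\"%s\"^^xsd:string", a$sex))
      } else {
        mnode <- sprintf("%s_meas_%s", rnode, a$mclass)
        emit(anode, "sio:hasMeasurement", mnode)
        emit(mnode, "rdf:type", "sio:Measurement")
        emit(mnode, "sio:hasValue", fmt_double(a$quantity$value))
        emit(mnode, "sio:hasUnit", sprintf("muo:%s", a$quantity$unit))
      }
    }
    for (key in names(rec$expert_flags)) {
      emit(rnode, sprintf("cardio:expertFlag_%s", key),
           sprintf("\"%d\"^^xsd:integer", as.integer(rec$expert_flags[[key]])))
    }
    if (!is.null(rec$expert_ternary)) {
      emit(rnode, "cardio:expertTernary",
           sprintf("\"%d\"^^xsd:integer", rec$expert_ternary))
    }
    for (f in c("smoker", "diabetic", "bp_treated")) {
      if (!is.null(rec[[f]])) {
        emit(rnode, sprintf("cardio:%s", f),
             sprintf("\"%s\"^^xsd:boolean",
                     if (isTRUE(rec[[f]])) "true" else "false"))
      }
    }
  }
  paste(c(lines, ""), collapse = "\n")
}

parse_turtle_object <- function(o) {
  m <- regmatches(o, regexec('^"(.*)"\\^\\^xsd:(\\w+)$', o))[[1]]
  if (length(m) == 3L) {
    val <- switch(m[[3]],
                  double = , decimal = , float = as.numeric(m[[2]]),
                  integer = as.integer(m[[2]]),
                  boolean = identical(m[[2]], "true"),
                  m[[2]])
    return(list(kind = "literal", value = val))
  }
  list(kind = "iri", value = o)
}

#' Parse Turtle patient records
#'
#' Inverse of [write_rdf()] on its own output profile (one triple per
#' line, prefixed names, typed literals). A measurement node missing
#' `sio:hasValue` or `sio:hasUnit`, or an attribute typed with an unknown
#' measurement class, is an error naming the offending node/class.
#'
#' @param text Turtle text (single string or character vector of lines),
#'   or a path to a Turtle file.
#' @return List of [patient_record()]s.
#' @export
read_rdf <- function(text) {
  if (length(text) == 1L && !grepl("\n", text, fixed = TRUE) &&
      file.exists(text)) {
    text <- readLines(text, warn = FALSE)
  }
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "@prefix") &
                   !startsWith(lines, "#")]
  triples <- list()
  for (ln in lines) {
    if (!endsWith(ln, ".")) {
      stop("malformed statement: ", ln, call. = FALSE)
    }
    body <- trimws(substr(ln, 1L, nchar(ln) - 1L))
    # subject and predicate contain no spaces; object may (string literal)
    sp <- regmatches(body, regexec("^(\\S+)\\s+(\\S+)\\s+(.+)$", body))[[1]]
    if (length(sp) != 4L) stop("malformed triple: ", ln, call. = FALSE)
    triples[[length(triples) + 1L]] <-
      list(s = sp[[2]], p = sp[[3]], o = trimws(sp[[4]]))
  }
  if (length(triples) == 0L) return(list())

  subj <- vapply(triples, `[[`, character(1), "s")
  pred <- vapply(triples, `[[`, character(1), "p")
  obj <- vapply(triples, `[[`, character(1), "o")

  rec_nodes <- unique(subj[pred == "rdf:type" & obj == "cardio:PatientRecord"])
  classes <- measurement_classes()$name
  records <- vector("list", length(rec_nodes))

  pv <- function(node, p) obj[subj == node & pred == p]

  for (k in seq_along(rec_nodes)) {
    rnode <- rec_nodes[[k]]
    id <- pv(rnode, "cardio:recordID")
    id <- if (length(id) > 0) parse_turtle_object(id[[1]])$value else rnode
    rec <- patient_record(id)
    for (anode in pv(rnode, "sio:hasAttribute")) {
      atype <- pv(anode, "rdf:type")
      atype <- atype[startsWith(atype, "cardio:")]
      if (length(atype) == 0L) {
        stop("attribute node ", anode, " has no cardio type", call. = FALSE)
      }
      mclass <- sub("^cardio:", "", atype[[1]])
      if (!mclass %in% classes) {
        stop("unknown measurement class: ", mclass, call. = FALSE)
      }
      if (identical(mclass, "Sex")) {
        sx <- pv(anode, "cardio:hasSexValue")
        if (length(sx) == 0L) {
          stop("Sex attribute ", anode, " missing value", call. = FALSE)
        }
        rec <- set_sex(rec, parse_turtle_object(sx[[1]])$value)
      } else {
        mnode <- pv(anode, "sio:hasMeasurement")
        if (length(mnode) == 0L) {
          stop("attribute node ", anode, " missing sio:hasMeasurement",
               call. = FALSE)
        }
        val <- pv(mnode[[1]], "sio:hasValue")
        if (length(val) == 0L) {
          stop("measurement node ", mnode[[1]], " missing sio:hasValue",
               call. = FALSE)
        }
        unit <- pv(mnode[[1]], "sio:hasUnit")
        if (length(unit) == 0L) {
          stop("measurement node ", mnode[[1]], " missing sio:hasUnit",
               call. = FALSE)
        }
        rec <- set_attribute(
          rec, mclass,
          quantity(parse_turtle_object(val[[1]])$value,
                   sub("^muo:", "", unit[[1]])))
      }
    }
    flag_preds <- unique(pred[subj == rnode &
                                startsWith(pred, "cardio:expertFlag_")])
    if (length(flag_preds) > 0L) {
      flags <- vapply(flag_preds, function(p) {
        as.numeric(parse_turtle_object(pv(rnode, p)[[1]])$value)
      }, numeric(1))
      names(flags) <- sub("^cardio:expertFlag_", "", flag_preds)
      rec$expert_flags <- flags
    }
    tern <- pv(rnode, "cardio:expertTernary")
    if (length(tern) > 0L) {
      rec$expert_ternary <- as.integer(parse_turtle_object(tern[[1]])$value)
    }
    for (f in c("smoker", "diabetic", "bp_treated")) {
      v <- pv(rnode, sprintf("cardio:%s", f))
      if (length(v) > 0L) rec[[f]] <- parse_turtle_object(v[[1]])$value
    }
    records[[k]] <- rec
  }
  records
}
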
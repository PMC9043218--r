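# Column registry for ADR report tables ---------------------------------

CAUSALITY_COLS <- paste0("causality_assessment_", 1:5)
SEVERITY_COLS  <- paste0("severity_assessment_", 1:6)
PREDICTOR_COLS <- c(CAUSALITY_COLS, SEVERITY_COLS)
FLAG_COLS      <- c("new_ade", "serious_ade", "gender", "suspect")
ASSESS_COLS    <- c("r_assess", "ri_assess", "muni_assess", "prov_assess")
REQUIRED_COLS  <- c(PREDICTOR_COLS, FLAG_COLS, ASSESS_COLS)

BOOL_TRUE  <- c("1", "true", "TRUE", "True")
BOOL_FALSE <- c("0", "false", "FALSE", "False")

#' Names of the model predictor columns
#'
#' The eleven Boolean assessment items used as predictors of the causality
#' category: five causality items (plausible time relationship, match with
#' known reaction types, response to withdrawal, rechallenge, alternative
#' explanation) and six severity items (death; carcinogenic/teratogenic;
#' disability or organ damage; life threatening; hospitalization; other
#' significant medical events).
#'
#' @return Character vector of length 11.
#' @export
predictor_names <- function() PREDICTOR_COLS

#' Column groups of an ADR report table
#'
#' @return A named list with elements `predictors` (11 Boolean items),
#'   `flags` (new/serious ADE, gender, suspect-drug indicator) and
#'   `assessments` (the four recorded ordinal causality assessments:
#'   reporter, reporter's institute, municipal and provincial level).
#' @export
report_columns <- function() {
  list(predictors = PREDICTOR_COLS, flags = FLAG_COLS, assessments = ASSESS_COLS)
}

is_bool01 <- function(x) is.numeric(x) & !is.na(x) & x %in% c(0, 1)

parse_bool_chr <- function(x) {
  out <- rep(NA_integer_, length(x))
  out[x %in% BOOL_TRUE]  <- 1L
  out[x %in% BOOL_FALSE] <- 0L
  out
}

# Ordinal causality codes: 1..5 increasing certainty, -1 = not assessed.
parse_ordinal_chr <- function(x) {
  blank <- is.na(x) | trimws(x) == ""
  out <- suppressWarnings(as.integer(x))
  out[blank] <- -1L
  bad <- !blank & (is.na(out) | !(out %in% c(-1L, 1:5)))
  attr(out, "bad") <- which(bad)
  attr(out, "blank") <- which(blank)
  out
}

#' Read an ADR report table from CSV
#'
#' Reads a UTF-8, comma-separated report extract with a mandatory header row
#' and validates it against the report schema.  Boolean columns accept
#' `0/1/true/false/TRUE/FALSE`; the four causality assessments must be coded
#' on the ordinal 1--5 certainty scale with `-1` for "not assessed" (blank
#' cells are mapped to `-1` with a warning).  Columns outside the declared
#' schema are preserved verbatim as text, never dropped.
#'
#' @param path Path to a CSV file.
#' @return A [tibble::tibble] with one row per report; source path and row
#'   count are recorded in the `"provenance"` attribute.
#' @seealso [write_reports()], [validate_reports()]
#' @export
read_reports <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) {
    tab <- empty_report_table()
    attr(tab, "provenance") <- list(source = path, n = 0L)
    return(tab)
  }
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         na.strings = character(0), fileEncoding = "UTF-8")
  missing_cols <- setdiff(REQUIRED_COLS, names(raw))
  if (length(missing_cols) > 0) {
    stop("schema error: missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  out <- tibble::as_tibble(raw)
  for (col in c(PREDICTOR_COLS, FLAG_COLS)) {
    parsed <- parse_bool_chr(raw[[col]])
    if (anyNA(parsed)) {
      row <- which(is.na(parsed))[1]
      stop(sprintf("validation error: invalid Boolean value '%s' (row %d, %s)",
                   raw[[col]][row], row, col))
    }
    out[[col]] <- parsed
  }
  for (col in ASSESS_COLS) {
    parsed <- parse_ordinal_chr(raw[[col]])
    bad <- attr(parsed, "bad")
    if (length(bad) > 0) {
      stop(sprintf("validation error: invalid causality code '%s' (row %d, %s)",
                   raw[[col]][bad[1]], bad[1], col))
    }
    if (length(attr(parsed, "blank")) > 0) {
      warning(sprintf("%d blank cell(s) in %s read as -1 (not assessed)",
                      length(attr(parsed, "blank")), col))
    }
    attributes(parsed) <- NULL
    out[[col]] <- parsed
  }
  viol <- validate_reports(out)
  if (any(viol$severity == "warning")) {
    warning("consistency warning(s) in ", path, ": ",
            paste(utils::head(viol$message[viol$severity == "warning"], 3),
                  collapse = "; "))
  }
  attr(out, "provenance") <- list(source = path, n = nrow(out))
  out
}

empty_report_table <- function() {
  cols <- c(
    stats::setNames(rep(list(integer()), length(c(PREDICTOR_COLS, FLAG_COLS))),
                    c(PREDICTOR_COLS, FLAG_COLS)),
    stats::setNames(rep(list(integer()), length(ASSESS_COLS)), ASSESS_COLS)
  )
  tibble::as_tibble(cols)
}

#' Write an ADR report table to CSV
#'
#' Inverse of [read_reports()]: Boolean columns are written canonically as
#' `0/1`, ordinal assessments as integers (with `-1` for "not assessed"),
#' and any extra columns verbatim, so that a write/read round trip
#' reproduces the table field-for-field.
#'
#' @param table A report table (data frame following the report schema).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_reports <- function(table, path) {
  stopifnot(is.data.frame(table))
  out <- as.data.frame(table)
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8",
                   quote = TRUE, na = "")
  invisible(path)
}

#' Validate a report table against the schema
#'
#' Checks every schema invariant and reports violations without throwing:
#' required columns present, predictors and flags in `{0,1}`, assessments in
#' `{-1, 1..5}`, and consistency of the serious-ADE flag with the logical OR
#' of the six severity items (an inconsistency is a warning-severity
#' descriptor, since real extracts carry the flag as recorded).
#'
#' @param table A data frame to check.
#' @return A tibble of violation descriptors with columns `row` (NA for
#'   table-level problems), `column`, `rule`, `severity` (`"error"` or
#'   `"warning"`) and `message`; zero rows iff all invariants hold.
#' @export
validate_reports <- function(table) {
  desc <- list()
  add <- function(row, column, rule, severity, message) {
    desc[[length(desc) + 1]] <<- tibble::tibble(
      row = as.integer(row), column = column, rule = rule,
      severity = severity, message = message)
  }
  missing_cols <- setdiff(REQUIRED_COLS, names(table))
  for (col in missing_cols) {
    add(NA, col, "required_column", "error", paste0("missing column ", col))
  }
  for (col in setdiff(c(PREDICTOR_COLS, FLAG_COLS), missing_cols)) {
    bad <- which(!is_bool01(as.numeric(table[[col]])))
    for (row in bad) {
      add(row, col, "boolean_domain", "error",
          sprintf("non-Boolean value '%s' (row %d, %s)", table[[col]][row], row, col))
    }
  }
  for (col in setdiff(ASSESS_COLS, missing_cols)) {
    v <- suppressWarnings(as.integer(table[[col]]))
    bad <- which(is.na(v) | !(v %in% c(-1L, 1:5)))
    for (row in bad) {
      add(row, col, "ordinal_domain", "error",
          sprintf("invalid causality code '%s' (row %d, %s)", table[[col]][row], row, col))
    }
  }
  if (length(missing_cols) == 0 && nrow(table) > 0) {
    sev <- as.matrix(table[SEVERITY_COLS])
    storage.mode(sev) <- "numeric"
    any_sev <- as.integer(rowSums(sev, na.rm = TRUE) > 0)
    flag <- suppressWarnings(as.numeric(table[["serious_ade"]]))
    bad <- which(!is.na(flag) & flag %in% c(0, 1) & any_sev != flag)
    for (row in bad) {
      add(row, "serious_ade", "severity_consistency", "warning",
          sprintf("serious_ade=%d but OR of severity items is %d (row %d)",
                  as.integer(flag[row]), any_sev[row], row))
    }
  }
  if (length(desc) == 0) {
    return(tibble::tibble(row = integer(), column = character(),
                          rule = character(), severity = character(),
                          message = character()))
  }
  do.call(rbind, desc)
}
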
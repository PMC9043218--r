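# Triage: model extension, brushing-style filters, preset workflows ------

#' Extend a report table with model assessment and warning signal
#'
#' Adds (or overwrites) columns `auto_assess` (predicted category),
#' `risk_s` and `risk_t` (warning signal components).  Original columns
#' and row order are untouched, and re-running produces identical values.
#' Reports whose reference assessment is missing (`-1`) get `NA` risk
#' columns.
#'
#' @param table Report table following the schema.
#' @param model Fitted model exposing [category_probabilities()].
#' @param variant Signal formula variant, see [compute_s()].
#' @param y0_source Which recorded assessment serves as the reference
#'   `Y0`; default `"ri_assess"` (the reporter's institute).
#' @return The extended table.
#' @export
extend_reports <- function(table, model,
                           variant = c("table3_consistent", "eq8_literal"),
                           y0_source = c("ri_assess", "r_assess",
                                         "muni_assess", "prov_assess")) {
  variant <- match.arg(variant)
  y0_source <- match.arg(y0_source)
  miss <- setdiff(c(predictor_names(), "serious_ade", y0_source), names(table))
  if (length(miss) > 0) {
    stop("schema mismatch: missing column(s): ", paste(miss, collapse = ", "))
  }
  auto <- predict_category(model, table)
  sig <- compute_signal(auto, table[[y0_source]],
                        as.logical(table[["serious_ade"]]), variant)
  out <- table
  out$auto_assess <- auto
  out$risk_s <- sig$s
  out$risk_t <- sig$t
  attr(out, "signal_variant") <- variant
  attr(out, "y0_source") <- y0_source
  out
}

FILTER_OPS <- c("eq", "ne", "lt", "le", "gt", "ge", "in_set", "between")

#' A single brushing-style filter predicate
#'
#' @param column Column name the predicate applies to.
#' @param op One of `eq, ne, lt, le, gt, ge, in_set, between`.
#' @param value Constant (or value set for `in_set`, `c(lo, hi)` for
#'   `between`).
#' @return A `filter_predicate` object.
#' @export
filter_predicate <- function(column, op, value) {
  op <- match.arg(op, FILTER_OPS)
  if (op == "between") {
    if (length(value) != 2 || value[1] > value[2]) {
      stop("between requires value = c(lo, hi) with lo <= hi")
    }
  }
  structure(list(column = column, op = op, value = value),
            class = "filter_predicate")
}

#' A triage query: a conjunction of predicates
#'
#' Mirrors brushing on parallel coordinates (one range per axis, all
#' simultaneously active); an empty query selects everything.
#'
#' @param ... [filter_predicate()] objects (or a single list of them).
#' @return A `triage_query` object.
#' @export
triage_query <- function(...) {
  preds <- list(...)
  if (length(preds) == 1 && is.list(preds[[1]]) &&
      !inherits(preds[[1]], "filter_predicate")) {
    preds <- preds[[1]]
  }
  if (!all(vapply(preds, inherits, logical(1), "filter_predicate"))) {
    stop("all arguments must be filter_predicate objects")
  }
  structure(list(predicates = preds), class = "triage_query")
}

#' Parse `"column op value"` strings into predicates
#'
#' Accepts the compact syntax used by the command-line interface, e.g.
#' `"risk_s<-8"`, `"suspect=1"`, `"prov_assess>=4"`, `"muni_assess!=3"`.
#'
#' @param ... Character predicate strings.
#' @return A [triage_query()].
#' @export
parse_predicates <- function(...) {
  strs <- unlist(list(...), use.names = FALSE)
  op_map <- c("<=" = "le", ">=" = "ge", "!=" = "ne", "=" = "eq",
              "==" = "eq", "<" = "lt", ">" = "gt")
  preds <- lapply(strs, function(s) {
    m <- regmatches(s, regexec("^\\s*([A-Za-z_][A-Za-z0-9_]*)\\s*(<=|>=|!=|==|=|<|>)\\s*(-?[0-9.]+)\\s*$", s))[[1]]
    if (length(m) == 0) stop("cannot parse predicate: ", s)
    filter_predicate(m[2], unname(op_map[m[3]]), as.numeric(m[4]))
  })
  triage_query(preds)
}

apply_predicate <- function(table, p) {
  if (!p$column %in% names(table)) stop("unknown column: ", p$column)
  x <- table[[p$column]]
  keep <- switch(p$op,
    eq = x == p$value, ne = x != p$value,
    lt = x < p$value, le = x <= p$value,
    gt = x > p$value, ge = x >= p$value,
    in_set = x %in% p$value,
    between = x >= p$value[1] & x <= p$value[2])
  keep & !is.na(keep)   # undefined signals never match a brush
}

#' Filter reports with a triage query
#'
#' Returns the rows satisfying every predicate (conjunction), in their
#' original order.  Rows with `NA` in a touched column (e.g. an undefined
#' warning signal) are excluded.
#'
#' @param table Report table (extended with [extend_reports()] if
#'   predicates touch `auto_assess`/`risk_*` columns).
#' @param query A [triage_query()].
#' @return The filtered table; the number of matches is attached as
#'   attribute `"n_matched"`.
#' @export
filter_reports <- function(table, query) {
  stopifnot(inherits(query, "triage_query"))
  keep <- rep(TRUE, nrow(table))
  for (p in query$predicates) keep <- keep & apply_predicate(table, p)
  out <- table[keep, , drop = FALSE]
  attr(out, "n_matched") <- sum(keep)
  out
}

#' Preset triage queries for the two reference review workflows
#'
#' Two canned queries reproducing the exploration workflows the warning
#' signal was designed for:
#' \describe{
#'   \item{`opposite_assessments`}{Suspect drug, strongly negative signal
#'     (`risk_s < -8`), provincial assessment above "possible" while
#'     reporter, institute and municipal assessments are at or below it —
#'     reports where the model and upper-tier experts contradict the
#'     reporting side.}
#'   \item{`unreviewed_certain`}{Suspect drug, no provincial assessment
#'     (`prov_assess = -1`), model assessment "certain"
#'     (`auto_assess = 5`) — high-confidence reports no expert reviewed.}
#' }
#'
#' @return Named list of two [triage_query()] objects.
#' @export
triage_presets <- function() {
  list(
    opposite_assessments = triage_query(
      filter_predicate("suspect", "eq", 1),
      filter_predicate("risk_s", "lt", -8),
      filter_predicate("prov_assess", "gt", 3),
      filter_predicate("r_assess", "le", 3),
      filter_predicate("ri_assess", "le", 3),
      filter_predicate("muni_assess", "le", 3)),
    unreviewed_certain = triage_query(
      filter_predicate("suspect", "eq", 1),
      filter_predicate("prov_assess", "eq", -1),
      filter_predicate("auto_assess", "eq", 5))
  )
}
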
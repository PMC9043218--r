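# Warning signal lambda = (s, t) ----------------------------------------
#
# Per-report score combining: d, the signed degree of disagreement between
# the model assessment Y and a recorded human assessment Y0 (positive when
# the two agree on which side of "possible" the report falls, negative
# when they take opposite sides); r, a severity weight (1 normal / 4
# serious ADE, chosen so normal- and serious-report scores do not
# overlap); and t = Y - Y0, the raw difference.
#
# Two s formulas ship because the published sources are internally
# inconsistent: the literal rule s = r*(d+1) does not reproduce the
# published worked examples, while applying the +1 offset only for d >= 0
# (variant "table3_consistent", the default) reproduces every one of them
# and the stated serious-report extreme of +/-16.

SIGNAL_VARIANTS <- c("table3_consistent", "eq8_literal")

check_cat <- function(y, arg) {
  if (any(!(y %in% c(-1L, 1:5)))) {
    stop(arg, " must contain causality categories in 1..5 (or -1 missing)")
  }
}

#' Disagreement score d between two assessments
#'
#' `|Y - Y0|` when both assessments fall strictly on the same side of the
#' middle category 3; `Y + Y0 - 6` when either equals 3; `-|Y - Y0|` when
#' they fall on opposite sides.  Ranges over `{-4, ..., 2}`.
#'
#' @param y Model assessment (1..5, or -1 missing).
#' @param y0 Recorded human assessment (1..5, or -1 missing).
#' @return Integer vector; `NA` where either input is missing.
#' @export
compute_d <- function(y, y0) {
  y <- as.integer(y); y0 <- as.integer(y0)
  check_cat(y, "y"); check_cat(y0, "y0")
  prod <- (y - 3L) * (y0 - 3L)
  d <- ifelse(prod > 0L, abs(y - y0),
              ifelse(prod == 0L, y + y0 - 6L, -abs(y - y0)))
  d[y == -1L | y0 == -1L] <- NA_integer_
  as.integer(d)
}

#' Severity weight r
#'
#' @param serious Logical (or 0/1) serious-ADE flag.
#' @return Integer vector: 1 for a normal ADE, 4 for a serious ADE.
#' @export
compute_r <- function(serious) {
  ifelse(as.logical(serious), 4L, 1L)
}

#' Signal component s from d and r
#'
#' `variant = "eq8_literal"`: `s = r * (d + 1)` for every d.
#' `variant = "table3_consistent"` (default): `s = r * (d + 1)` for
#' `d >= 0` and `s = r * d` for `d < 0` — the only reading that reproduces
#' the published worked examples and the serious-report extreme of 16.
#'
#' @param d Disagreement score from [compute_d()].
#' @param r Severity weight from [compute_r()].
#' @param variant One of `"table3_consistent"`, `"eq8_literal"`.
#' @return Integer vector; `NA` where `d` is missing.
#' @export
compute_s <- function(d, r, variant = c("table3_consistent", "eq8_literal")) {
  variant <- match.arg(variant)
  d <- as.integer(d); r <- as.integer(r)
  if (any(!(r %in% c(1L, 4L)))) stop("r must be 1 or 4")
  if (variant == "eq8_literal") {
    as.integer(r * (d + 1L))
  } else {
    as.integer(ifelse(d >= 0L, r * (d + 1L), r * d))
  }
}

#' Signal component t: raw assessment difference
#'
#' @inheritParams compute_d
#' @return Integer vector `y - y0` in `[-4, 4]`; `NA` where missing.
#' @export
compute_t <- function(y, y0) {
  y <- as.integer(y); y0 <- as.integer(y0)
  check_cat(y, "y"); check_cat(y0, "y0")
  t <- y - y0
  t[y == -1L | y0 == -1L] <- NA_integer_
  t
}

#' Warning signal for one or more reports
#'
#' Composes [compute_d()], [compute_r()], [compute_s()] and [compute_t()]
#' into the tuple `(s, t)` plus intermediates.  Reports with a missing
#' model or reference assessment get an undefined (`NA`) signal.
#'
#' @inheritParams compute_d
#' @param serious Serious-ADE flag per report.
#' @param variant Signal formula variant, see [compute_s()].
#' @return Tibble with columns `y`, `y0`, `serious`, `d`, `r`, `s`, `t`,
#'   `variant`.
#' @export
compute_signal <- function(y, y0, serious,
                           variant = c("table3_consistent", "eq8_literal")) {
  variant <- match.arg(variant)
  n <- max(length(y), length(y0), length(serious))
  y <- rep_len(as.integer(y), n)
  y0 <- rep_len(as.integer(y0), n)
  serious <- rep_len(serious, n)
  d <- compute_d(y, y0)
  r <- compute_r(serious)
  s <- rep(NA_integer_, n)
  ok <- !is.na(d)
  s[ok] <- compute_s(d[ok], r[ok], variant)
  tibble::tibble(y = y, y0 = y0, serious = as.logical(serious),
                 d = d, r = r, s = s, t = compute_t(y, y0),
                 variant = variant)
}

#' Attainable values of the signal component s
#'
#' Exact set of `s` over all 25 assessment pairs `(Y, Y0)` in `{1..5}^2`
#' for the given severity and formula variant, by exhaustive enumeration.
#'
#' @inheritParams compute_s
#' @param serious Single logical: serious ADE?
#' @return Sorted integer vector of attainable `s` values.
#' @export
attainable_values <- function(variant = c("table3_consistent", "eq8_literal"),
                              serious = FALSE) {
  variant <- match.arg(variant)
  grid <- expand.grid(y = 1:5, y0 = 1:5)
  sig <- compute_signal(grid$y, grid$y0, rep(serious, nrow(grid)), variant)
  sort(unique(sig$s))
}
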
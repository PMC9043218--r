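# Static parallel-coordinates export -------------------------------------

# Default axis ordering for parallel-coordinates viewing: report flags,
# the four recorded assessments, suspect-drug indicator, then the model
# assessment and the two warning-signal components.
VIZ_AXES <- c("new_ade", "serious_ade", "gender",
              "r_assess", "ri_assess", "muni_assess", "prov_assess",
              "suspect", "auto_assess", "risk_s", "risk_t")

# Red-yellow-blue diverging map over the causality categories:
# 1 (unassessable, red) ... 5 (certain, blue).
CATEGORY_COLORS <- c("1" = "#D7191C", "2" = "#FDAE61", "3" = "#FFFFBF",
                     "4" = "#ABD9E9", "5" = "#2C7BB6")

#' Export an extended report table for parallel-coordinates viewing
#'
#' Writes a JSON document carrying the default axis ordering, the
#' category-to-color mapping (category 1 red through 5 blue) and one
#' record per row, plus (optionally) a self-contained static HTML file
#' rendering a non-interactive parallel-coordinates snapshot of the same
#' data.  The JSON contract lets any front end (e.g. a D3 application)
#' consume the table.
#'
#' @param table Report table extended with [extend_reports()].
#' @param json_path Output path for the JSON document.
#' @param html_path Optional output path for the HTML snapshot.
#' @return `json_path`, invisibly.
#' @export
export_viz <- function(table, json_path, html_path = NULL) {
  miss <- setdiff(VIZ_AXES, names(table))
  if (length(miss) > 0) {
    stop("table must be extended before export; missing column(s): ",
         paste(miss, collapse = ", "))
  }
  rows <- as.data.frame(table[VIZ_AXES])
  doc <- list(axes = VIZ_AXES,
              color_by = "auto_assess",
              color_map = as.list(CATEGORY_COLORS),
              n = nrow(rows),
              rows = rows)
  jsonlite::write_json(doc, json_path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  if (!is.null(html_path)) {
    writeLines(viz_html(rows), html_path, useBytes = TRUE)
  }
  invisible(json_path)
}

viz_html <- function(rows) {
  w <- 1000; h <- 420; pad <- 60
  k <- length(VIZ_AXES)
  xs <- pad + (seq_len(k) - 1) * (w - 2 * pad) / (k - 1)
  scale_y <- function(v) {
    v <- as.numeric(v)
    rng <- range(v, na.rm = TRUE)
    if (!is.finite(rng[1]) || diff(rng) == 0) rng <- c(rng[1] - 1, rng[1] + 1)
    (h - pad) - (v - rng[1]) / diff(rng) * (h - 2 * pad)
  }
  Y <- vapply(VIZ_AXES, function(a) scale_y(rows[[a]]), numeric(nrow(rows)))
  if (nrow(rows) == 1) Y <- matrix(Y, 1)
  col <- unname(CATEGORY_COLORS[as.character(rows$auto_assess)])
  col[is.na(col)] <- "#999999"
  polys <- vapply(seq_len(nrow(rows)), function(i) {
    ok <- !is.na(Y[i, ])
    pts <- paste(sprintf("%.1f,%.1f", xs[ok], Y[i, ok]), collapse = " ")
    sprintf('<polyline points="%s" fill="none" stroke="%s" stroke-opacity="0.55" stroke-width="1"/>',
            pts, col[i])
  }, character(1))
  axes <- vapply(seq_len(k), function(j) {
    sprintf(paste0('<line x1="%.1f" y1="%d" x2="%.1f" y2="%d" stroke="#333"/>',
                   '<text x="%.1f" y="%d" font-size="9" text-anchor="middle" ',
                   'transform="rotate(-30 %.1f %d)">%s</text>'),
            xs[j], pad, xs[j], h - pad, xs[j], h - pad + 28, xs[j],
            h - pad + 28, VIZ_AXES[j])
  }, character(1))
  c("<!DOCTYPE html>",
    "<html><head><meta charset=\"utf-8\"/><title>ADR report triage snapshot</title></head>",
    "<body style=\"font-family:sans-serif\">",
    sprintf("<h3>Parallel-coordinates snapshot (%d reports)</h3>", nrow(rows)),
    "<p>Color: model-assessed causality category, 1 (red) through 5 (blue).</p>",
    sprintf('<svg width="%d" height="%d" xmlns="http://www.w3.org/2000/svg">', w, h),
    polys, axes, "</svg>", "</body></html>")
}
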
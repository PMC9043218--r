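# Accuracy, per-class F1, and one-vs-rest multiclass ROC/AUC -------------

#' Classification accuracy
#'
#' @param pred,truth Equal-length vectors of causality categories.
#' @return Fraction of exact matches, in `[0, 1]`.
#' @export
accuracy <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("length mismatch")
  if (length(pred) == 0) stop("empty input")
  mean(pred == truth)
}

#' Per-class F1 scores
#'
#' Harmonic mean of precision and recall for each causality category.
#' A category with zero predicted and zero true positives scores 0, the
#' convention used when some categories never occur.
#'
#' @inheritParams accuracy
#' @param classes Categories to report (default 1..5).
#' @return Named numeric vector of F1 values in `[0, 1]`.
#' @export
f1_per_class <- function(pred, truth, classes = 1:5) {
  if (length(pred) != length(truth)) stop("length mismatch")
  out <- vapply(classes, function(cl) {
    tp <- sum(pred == cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    fn <- sum(pred != cl & truth == cl)
    if (2 * tp + fp + fn == 0) return(0)
    2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  stats::setNames(out, as.character(classes))
}

# Binary ROC sweep over tie-grouped thresholds.  Trapezoidal AUC over the
# tie-grouped curve equals the Mann-Whitney concordance probability with
# ties counted 1/2.
binary_roc <- function(score, pos) {
  P <- sum(pos); N <- sum(!pos)
  if (P == 0 || N == 0) return(list(curve = NULL, auc = NA_real_))
  ord <- order(score, decreasing = TRUE)
  s <- score[ord]; p <- pos[ord]
  last <- c(s[-1] != s[-length(s)], TRUE)   # last index of each tie block
  tpr <- cumsum(p)[last] / P
  fpr <- cumsum(!p)[last] / N
  curve <- cbind(fpr = c(0, fpr), tpr = c(0, tpr))
  auc <- sum(diff(curve[, 1]) * (curve[-1, 2] + curve[-nrow(curve), 2]) / 2)
  list(curve = curve, auc = auc)
}

#' One-vs-rest ROC curve and AUC for one category
#'
#' Uses the predicted probability of category `cls` as the score and
#' `truth == cls` as the positive indicator.  The AUC equals the
#' probability that a random positive outscores a random negative, ties
#' counting one half.  If the category is absent from (or fills all of)
#' the truth vector the AUC is undefined and returned as `NA`.
#'
#' @param probs `n x 5` matrix of category probabilities (rows sum to 1).
#' @param truth Integer categories in 1..5.
#' @param cls Category whose one-vs-rest curve is wanted.
#' @return List with `curve` (matrix of (fpr, tpr) points from (0,0) to
#'   (1,1), monotone in both coordinates) and `auc`.
#' @export
roc_ovr <- function(probs, truth, cls) {
  probs <- as.matrix(probs)
  if (nrow(probs) != length(truth)) stop("length mismatch")
  if (nrow(probs) == 0) stop("empty input")
  binary_roc(probs[, as.character(cls)], truth == cls)
}

#' Macro-averaged multiclass AUC
#'
#' Unweighted mean of the defined one-vs-rest AUCs; categories absent from
#' the truth are excluded from the average.
#'
#' @inheritParams roc_ovr
#' @param classes Categories considered (default 1..5).
#' @return A single number in `[0, 1]`.
#' @export
auc_macro <- function(probs, truth, classes = 1:5) {
  aucs <- vapply(classes, function(cl) roc_ovr(probs, truth, cl)$auc, numeric(1))
  if (all(is.na(aucs))) stop("no class has a defined one-vs-rest AUC")
  mean(aucs, na.rm = TRUE)
}

#' Micro-averaged multiclass AUC
#'
#' Binary AUC on the pooled indicator expansion: every (report, category)
#' pair contributes one score (the predicted probability) and one binary
#' label (whether that category is the true one).
#'
#' @inheritParams auc_macro
#' @return A single number in `[0, 1]`.
#' @export
auc_micro <- function(probs, truth, classes = 1:5) {
  probs <- as.matrix(probs)[, as.character(classes), drop = FALSE]
  truthmat <- outer(truth, classes, "==")
  binary_roc(as.vector(probs), as.vector(truthmat))$auc
}

#' Evaluate a model on a labeled test table
#'
#' Computes accuracy, per-class F1, one-vs-rest ROC curves and per-class,
#' macro and micro AUC for any model exposing [category_probabilities()]
#' (the ordinal model and both baselines go through this identical path,
#' so comparisons are apples-to-apples).
#'
#' @param model Fitted model.
#' @param test Non-empty labeled report table.
#' @param label Label column name.
#' @return An object of class `aca_evaluation`: list with `accuracy`,
#'   `f1_by_class`, `roc_by_class`, `auc_by_class`, `auc_macro`,
#'   `auc_micro`, `n_test`, `class_counts`.
#' @export
evaluate_model <- function(model, test, label = "prov_assess") {
  if (nrow(test) == 0) stop("empty test table")
  truth <- as.integer(test[[label]])
  if (any(!(truth %in% 1:5))) stop("labels must be in 1..5")
  probs <- category_probabilities(model, test)
  pred <- as.integer(max.col(probs, ties.method = "first"))
  rocs <- lapply(1:5, function(cl) roc_ovr(probs, truth, cl))
  aucs <- vapply(rocs, `[[`, numeric(1), "auc")
  structure(list(
    accuracy = accuracy(pred, truth),
    f1_by_class = f1_per_class(pred, truth),
    roc_by_class = stats::setNames(lapply(rocs, `[[`, "curve"), as.character(1:5)),
    auc_by_class = stats::setNames(aucs, as.character(1:5)),
    auc_macro = mean(aucs, na.rm = TRUE),
    auc_micro = auc_micro(probs, truth),
    n_test = length(truth),
    class_counts = stats::setNames(vapply(1:5, function(cl) sum(truth == cl),
                                          integer(1)), as.character(1:5))
  ), class = "aca_evaluation")
}

#' @export
print.aca_evaluation <- function(x, ...) {
  cat(sprintf("Evaluation on %d reports\n", x$n_test))
  cat(sprintf("  accuracy : %.4f\n", x$accuracy))
  cat("  F1 by class  :", paste(sprintf("%s=%.4f", names(x$f1_by_class),
                                        x$f1_by_class), collapse = "  "), "\n")
  cat("  AUC by class :",
      paste(sprintf("%s=%s", names(x$auc_by_class),
                    ifelse(is.na(x$auc_by_class), "NA",
                           sprintf("%.4f", x$auc_by_class))), collapse = "  "), "\n")
  cat(sprintf("  AUC macro: %.4f   AUC micro: %.4f\n", x$auc_macro, x$auc_micro))
  invisible(x)
}

#' Export ROC curves as a long data frame
#'
#' @param report An `aca_evaluation`.
#' @return Tibble with columns `class`, `fpr`, `tpr`, suitable for CSV
#'   export or plotting.
#' @export
roc_points <- function(report) {
  stopifnot(inherits(report, "aca_evaluation"))
  rows <- lapply(names(report$roc_by_class), function(cl) {
    cv <- report$roc_by_class[[cl]]
    if (is.null(cv)) return(NULL)
    tibble::tibble(class = cl, fpr = cv[, 1], tpr = cv[, 2])
  })
  do.call(rbind, rows)
}
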
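# Comparison classifiers: multinomial logistic regression and a CART
# decision tree over the same 11 Boolean predictors and 5-category outcome.
# Both are reduced at fit time to a plain parameter state (coefficient
# matrix / node table) and predict from that state, so serialization and
# reloading cannot change predictions.

new_baseline <- function(kind, params, baseline, levels, vars, hyper) {
  structure(list(kind = kind, params = params, baseline = baseline,
                 levels = as.integer(levels), vars = vars, hyper = hyper),
            class = "aca_baseline")
}

#' Fit the multinomial logistic regression baseline
#'
#' Softmax-linear model over the predictor items with an explicit reference
#' (baseline) category.  The default reference is category 4
#' ("probable/likely"); the choice does not change fitted probabilities
#' (softmax reparameterization) but does change reported coefficients.
#'
#' @inheritParams fit_ppo
#' @param baseline Reference causality category; must occur in the labels.
#' @param vars Predictor columns (default all 11).
#' @param maxit,reltol,abstol Optimizer controls passed to
#'   [nnet::multinom()]; the tight defaults make fitted probabilities
#'   invariant to the reference category to ~1e-8.
#' @return An `aca_baseline` of kind `"multinomial_logit"` exposing
#'   [category_probabilities()].
#' @export
fit_multinomial <- function(data, baseline = 4L, label = "prov_assess",
                            vars = predictor_names(), maxit = 5000L,
                            reltol = 1e-14, abstol = 1e-14) {
  y <- as.integer(data[[label]])
  if (any(!(y %in% 1:5))) stop("labels must be in 1..5")
  present <- sort(unique(y))
  if (!baseline %in% present) {
    stop("baseline category ", baseline, " absent from training labels")
  }
  lev_order <- c(baseline, setdiff(present, baseline))
  df <- as.data.frame(lapply(data[vars], as.numeric))
  df$.y <- factor(y, levels = lev_order)
  fit <- nnet::multinom(.y ~ ., data = df, trace = FALSE, maxit = maxit,
                        reltol = reltol, abstol = abstol)
  B <- stats::coef(fit)
  if (is.null(dim(B))) B <- matrix(B, 1, dimnames = list(fit$lev[2], names(B)))
  new_baseline("multinomial_logit",
               params = list(coef = B, lev_order = as.integer(lev_order)),
               baseline = as.integer(baseline), levels = present, vars = vars,
               hyper = list(maxit = maxit, reltol = reltol, abstol = abstol))
}

#' Fit the decision-tree baseline
#'
#' Axis-aligned binary CART classification tree (Gini impurity) over the
#' Boolean predictors; leaf class-frequency vectors serve as category
#' probabilities.  Defaults are deliberately transparent: no depth limit
#' beyond the implementation maximum, minimum leaf size 1, no complexity
#' pruning.  Deterministic given data and options.
#'
#' @inheritParams fit_multinomial
#' @param minsplit,minbucket,cp,maxdepth CART controls, see
#'   [rpart::rpart.control()].
#' @return An `aca_baseline` of kind `"decision_tree"`.
#' @export
fit_tree <- function(data, label = "prov_assess", vars = predictor_names(),
                     minsplit = 2L, minbucket = 1L, cp = 0, maxdepth = 30L) {
  y <- as.integer(data[[label]])
  if (any(!(y %in% 1:5))) stop("labels must be in 1..5")
  present <- sort(unique(y))
  hyper <- list(minsplit = minsplit, minbucket = minbucket, cp = cp,
                maxdepth = maxdepth)
  if (length(present) == 1) {
    params <- list(node = 1L, var = NA_character_, threshold = NA_real_,
                   direction = NA_integer_, probs = matrix(1, 1, 1),
                   lev_order = present)
    return(new_baseline("decision_tree", params, NA_integer_, present, vars,
                        hyper))
  }
  df <- as.data.frame(lapply(data[vars], as.numeric))
  df$.y <- factor(y, levels = present)
  fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                      parms = list(split = "gini"),
                      control = rpart::rpart.control(
                        minsplit = minsplit, minbucket = minbucket, cp = cp,
                        maxdepth = maxdepth, xval = 0,
                        maxcompete = 0, maxsurrogate = 0, usesurrogate = 0))
  new_baseline("decision_tree", params = tree_params(fit, present),
               baseline = NA_integer_, levels = present, vars = vars,
               hyper = hyper)
}

# Flatten an rpart object to a routable node table.  With maxcompete =
# maxsurrogate = 0 the rows of fit$splits align 1:1 with the internal
# nodes of fit$frame in frame order.
tree_params <- function(fit, present) {
  frame <- fit$frame
  K <- length(present)
  nodes <- as.integer(row.names(frame))
  is_leaf <- frame$var == "<leaf>"
  var <- as.character(frame$var); var[is_leaf] <- NA_character_
  thr <- rep(NA_real_, nrow(frame))
  dir <- rep(NA_integer_, nrow(frame))
  if (any(!is_leaf)) {
    sp <- fit$splits
    thr[!is_leaf] <- sp[, "index"]
    dir[!is_leaf] <- as.integer(sign(sp[, "ncat"]))  # -1: left gets x < thr
  }
  probs <- frame$yval2[, 1 + K + seq_len(K), drop = FALSE]
  list(node = nodes, var = var, threshold = thr, direction = dir,
       probs = unname(as.matrix(probs)), lev_order = as.integer(present))
}

route_tree <- function(params, X) {
  n <- nrow(X)
  out <- matrix(NA_real_, n, length(params$lev_order))
  lookup <- match(seq_len(2^16), params$node)  # node id -> row; sparse
  for (i in seq_len(n)) {
    node <- 1L
    repeat {
      row <- lookup[node]
      if (is.na(params$var[row])) break
      x <- X[i, params$var[row]]
      left <- if (params$direction[row] < 0) x < params$threshold[row]
              else x >= params$threshold[row]
      node <- if (left) 2L * node else 2L * node + 1L
    }
    out[i, ] <- params$probs[row, ]
  }
  out
}

#' @describeIn category_probabilities Baseline classifiers: softmax over the
#'   fitted coefficient matrix (multinomial logit) or leaf class
#'   frequencies (decision tree), expanded to the full 5-category space
#'   with zero probability for categories absent from training.
#' @export
category_probabilities.aca_baseline <- function(object, newdata, ...) {
  if (!is.data.frame(newdata)) newdata <- as.data.frame(as.list(newdata))
  miss <- setdiff(object$vars, names(newdata))
  if (length(miss) > 0) {
    stop("schema mismatch: data lacks predictor column(s): ",
         paste(miss, collapse = ", "))
  }
  X <- as.matrix(as.data.frame(lapply(newdata[object$vars], as.numeric)))
  pm <- object$params
  if (object$kind == "multinomial_logit") {
    eta <- cbind(1, X[, colnames(pm$coef)[-1], drop = FALSE]) %*% t(pm$coef)
    E <- cbind(1, exp(eta))             # reference category first
    P <- E / rowSums(E)
    lev <- pm$lev_order
  } else {
    P <- route_tree(pm, X)
    lev <- pm$lev_order
  }
  out <- matrix(0, nrow(P), 5, dimnames = list(NULL, as.character(1:5)))
  out[, as.character(lev)] <- P
  out
}

#' @export
print.aca_baseline <- function(x, ...) {
  cat(sprintf("Baseline model: %s over %d predictors, categories %s\n",
              x$kind, length(x$vars), paste(x$levels, collapse = ",")))
  if (x$kind == "multinomial_logit") {
    cat("  reference category:", x$baseline, "\n")
  } else {
    cat("  nodes:", length(x$params$node), "\n")
  }
  invisible(x)
}
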
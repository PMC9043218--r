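# Partial proportional-odds cumulative logit model ----------------------
#
# Sign convention (deliberate, documented): the model is
#     logit P(Y <= j | x) = theta_j + beta' x_parallel + tau_j' x_nonparallel
# so a POSITIVE coefficient pushes probability mass toward LOW (less
# certain) categories.  Many ordinal-regression packages use theta_j - eta;
# comparisons against them must flip the sign of the slopes.

#' Fitting options for the causality-assessment model
#'
#' @param max_iter Maximum number of quasi-Newton iterations per start.
#' @param grad_tol Convergence tolerance on the per-record gradient
#'   infinity norm, `max(abs(gradient))/n`.
#' @param ridge Non-negative ridge penalty on slope coefficients (cut
#'   points are never penalized); default 0.  Useful under quasi-complete
#'   separation.
#' @param seed Integer seed set before fitting (the default start is
#'   deterministic; the seed matters only for randomized restarts a caller
#'   may add).
#' @param empty_category Policy when an outcome category is absent from the
#'   training labels: `"error"` (default) stops naming the category, since
#'   its cut point is not identified; `"merge"` collapses the outcome scale
#'   to the categories present (absent categories get probability zero at
#'   prediction time) and records the mapping in the model.
#' @return An object of class `fit_options`.
#' @export
fit_options <- function(max_iter = 500L, grad_tol = 1e-6, ridge = 0,
                        seed = 1L, empty_category = c("error", "merge")) {
  stopifnot(max_iter >= 1, grad_tol > 0, ridge >= 0)
  structure(list(max_iter = as.integer(max_iter), grad_tol = grad_tol,
                 ridge = ridge, seed = as.integer(seed),
                 empty_category = match.arg(empty_category)),
            class = "fit_options")
}

#' Partition predictors into parallel and non-parallel sets
#'
#' The parallel set shares one slope across all cumulative logits (the
#' proportional-odds a.k.a. parallel assumption); each non-parallel
#' variable instead receives a separate coefficient per cut point.
#'
#' @param parallel,nonparallel Disjoint character vectors of predictor
#'   column names; their union is the set of predictors used by the model.
#' @return An object of class `model_partition`.
#' @export
model_partition <- function(parallel = predictor_names(),
                            nonparallel = character()) {
  parallel <- as.character(parallel); nonparallel <- as.character(nonparallel)
  if (length(intersect(parallel, nonparallel)) > 0) {
    stop("parallel and nonparallel variable sets must be disjoint")
  }
  if (anyDuplicated(c(parallel, nonparallel))) stop("duplicated variable names")
  structure(list(parallel = parallel, nonparallel = nonparallel),
            class = "model_partition")
}

# parameter vector layout: c(theta[1..Jm1], beta[1..p1], as.vector(tau[Jm1 x q]))
ppo_unpack <- function(par, Jm1, p1, q) {
  list(theta = par[seq_len(Jm1)],
       beta  = par[Jm1 + seq_len(p1)],
       tau   = matrix(par[Jm1 + p1 + seq_len(Jm1 * q)], Jm1, q))
}

ppo_eta_mat <- function(theta, beta, tau, Xp, Xn) {
  n <- max(nrow(Xp), nrow(Xn), 1L)
  eta <- matrix(theta, n, length(theta), byrow = TRUE)
  if (length(beta) > 0) eta <- eta + drop(Xp %*% beta)
  if (ncol(tau) > 0) eta <- eta + Xn %*% t(tau)
  eta
}

PROB_FLOOR <- 1e-12

ppo_negll <- function(par, Xp, Xn, y, Jm1, ridge) {
  pr <- ppo_unpack(par, Jm1, ncol(Xp), ncol(Xn))
  G <- cbind(0, stats::plogis(ppo_eta_mat(pr$theta, pr$beta, pr$tau, Xp, Xn)), 1)
  i <- seq_along(y)
  p <- G[cbind(i, y + 1L)] - G[cbind(i, y)]
  -sum(log(pmax(p, PROB_FLOOR))) +
    ridge * (sum(pr$beta^2) + sum(pr$tau^2))
}

ppo_negll_grad <- function(par, Xp, Xn, y, Jm1, ridge) {
  pr <- ppo_unpack(par, Jm1, ncol(Xp), ncol(Xn))
  n <- length(y)
  G <- cbind(0, stats::plogis(ppo_eta_mat(pr$theta, pr$beta, pr$tau, Xp, Xn)), 1)
  i <- seq_len(n)
  gup <- G[cbind(i, y + 1L)]
  glo <- G[cbind(i, y)]
  p <- pmax(gup - glo, PROB_FLOOR)
  W <- matrix(0, n, Jm1)
  up <- y <= Jm1                       # dP/d eta_y     (F(eta_y) term)
  W[cbind(i[up], y[up])] <- gup[up] * (1 - gup[up]) / p[up]
  lo <- y >= 2L                        # dP/d eta_{y-1} (-F(eta_{y-1}) term)
  W[cbind(i[lo], y[lo] - 1L)] <- W[cbind(i[lo], y[lo] - 1L)] -
    glo[lo] * (1 - glo[lo]) / p[lo]
  gtheta <- -colSums(W)
  gbeta <- if (ncol(Xp) > 0) -drop(crossprod(Xp, rowSums(W))) + 2 * ridge * pr$beta else numeric(0)
  gtau  <- if (ncol(Xn) > 0) as.vector(-crossprod(W, Xn)) + 2 * ridge * as.vector(pr$tau) else numeric(0)
  c(gtheta, gbeta, gtau)
}

ppo_design <- function(data, partition) {
  need <- c(partition$parallel, partition$nonparallel)
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    stop("schema mismatch: data lacks predictor column(s): ",
         paste(miss, collapse = ", "))
  }
  Xp <- as.matrix(as.data.frame(lapply(data[partition$parallel], as.numeric)))
  Xn <- as.matrix(as.data.frame(lapply(data[partition$nonparallel], as.numeric)))
  if (length(partition$parallel) == 0) Xp <- matrix(0, nrow(data), 0)
  if (length(partition$nonparallel) == 0) Xn <- matrix(0, nrow(data), 0)
  list(Xp = Xp, Xn = Xn)
}

#' Construct a causality-assessment model from known parameters
#'
#' Builds a fitted-model object directly from cut points and coefficients,
#' e.g. to specify the true model of a simulation or a hand-crafted toy.
#'
#' @param theta Numeric vector of J-1 cut points (4 for the full 5-category
#'   scale), non-decreasing for a valid proportional-odds baseline.
#' @param beta Named numeric vector of parallel slopes (names are predictor
#'   columns); may be empty.
#' @param tau Numeric matrix with J-1 rows and one column per non-parallel
#'   variable (column names are predictor columns); may be NULL.
#' @param levels Outcome categories the cut points refer to (default `1:5`).
#' @return A `ppo_fit` object usable with [category_probabilities()],
#'   [predict_category()] and the rest of the pipeline.
#' @export
ppo_model <- function(theta, beta = NULL, tau = NULL, levels = 1:5) {
  theta <- as.numeric(theta)
  if (is.null(beta)) beta <- stats::setNames(numeric(0), character(0))
  if (is.null(tau)) tau <- matrix(numeric(0), length(theta), 0)
  stopifnot(length(theta) == length(levels) - 1, nrow(tau) == length(theta))
  if (length(beta) > 0 && is.null(names(beta))) stop("beta must be named")
  if (ncol(tau) > 0 && is.null(colnames(tau))) stop("tau columns must be named")
  part <- model_partition(parallel = names(beta), nonparallel = colnames(tau))
  structure(list(
    theta = stats::setNames(theta, paste0("theta_", seq_along(theta))),
    beta = beta, tau = tau, partition = part,
    levels = as.integer(levels), log_likelihood = NA_real_,
    converged = TRUE, monotone_ok = all(diff(theta) >= 0),
    n_train = 0L, npar = length(theta) + length(beta) + length(tau),
    options = NULL, vcov = NULL, grad_norm = NA_real_
  ), class = "ppo_fit")
}

#' Fit the partial proportional-odds causality-assessment model
#'
#' Maximum-likelihood fit of the cumulative logit model
#' `logit P(Y <= j) = theta_j + beta' x_par + tau_j' x_nonpar` to labeled
#' ADR reports, by BFGS with analytic gradients started from the
#' closed-form intercept-only solution (cut points at the empirical
#' cumulative logits, zero slopes).  With an empty non-parallel set this is
#' exactly the proportional-odds model.
#'
#' Cut points are unconstrained; after fitting, monotonicity of the
#' cumulative probabilities across cut points is checked at every training
#' covariate pattern and recorded in `monotone_ok` (non-parallel
#' coefficients can produce crossing curves; predictions then floor
#' negative category probabilities at 1e-12 and renormalize, with a
#' warning).
#'
#' @param data Labeled report table; the label column must contain only
#'   categories in 1..5 (exclude unassessed records upstream).
#' @param partition A [model_partition()] over the predictor columns.
#' @param label Name of the label column (default `"prov_assess"`, the
#'   provincial expert assessment).
#' @param opts A [fit_options()] object.
#' @return An object of class `ppo_fit` with elements `theta`, `beta`,
#'   `tau`, `partition`, `levels`, `log_likelihood`, `converged`,
#'   `monotone_ok`, `n_train`, `npar`, `vcov`, `grad_norm`, `options`.
#'   Refitting with identical data, partition and options is bit-identical.
#' @export
fit_ppo <- function(data, partition = model_partition(),
                    label = "prov_assess", opts = fit_options()) {
  if (!label %in% names(data)) stop("label column not found: ", label)
  y_raw <- as.integer(data[[label]])
  if (any(is.na(y_raw)) || any(!(y_raw %in% c(-1L, 1:5)))) {
    stop("labels must be causality categories in 1..5")
  }
  if (any(y_raw == -1L)) {
    stop("unassessed labels (-1) present; exclude missing-label records upstream")
  }
  full_levels <- 1:5
  present <- sort(unique(y_raw))
  if (length(setdiff(full_levels, present)) > 0) {
    absent <- setdiff(full_levels, present)
    if (opts$empty_category == "error") {
      stop("outcome category(ies) absent from training data: ",
           paste(absent, collapse = ", "),
           " (cut points unidentified; use empty_category = \"merge\")")
    }
  }
  levels_used <- present
  J <- length(levels_used)
  if (J < 2) stop("need at least two outcome categories")
  y <- match(y_raw, levels_used)
  des <- ppo_design(data, partition)
  Xp <- des$Xp; Xn <- des$Xn
  Jm1 <- J - 1L
  npar <- Jm1 + ncol(Xp) + Jm1 * ncol(Xn)
  n <- length(y)
  if (n < npar) stop("fewer records (", n, ") than free parameters (", npar, ")")

  cf <- cumsum(tabulate(y, J)) / n
  theta0 <- stats::qlogis(pmin(pmax(cf[seq_len(Jm1)], 1e-10), 1 - 1e-10))
  par0 <- c(theta0, rep(0, ncol(Xp)), rep(0, Jm1 * ncol(Xn)))

  set.seed(opts$seed)
  par <- par0
  res <- NULL
  for (round in 1:3) {
    res <- stats::optim(par, ppo_negll, ppo_negll_grad, Xp = Xp, Xn = Xn,
                        y = y, Jm1 = Jm1, ridge = opts$ridge,
                        method = "BFGS",
                        control = list(maxit = opts$max_iter, reltol = 1e-14))
    par <- res$par
    g <- ppo_negll_grad(par, Xp, Xn, y, Jm1, opts$ridge)
    if (max(abs(g)) / n <= opts$grad_tol) break
  }
  grad_norm <- max(abs(g)) / n
  converged <- grad_norm <= opts$grad_tol
  if (!converged) {
    warning(sprintf("fit did not reach gradient tolerance (%.2e > %.2e)",
                    grad_norm, opts$grad_tol))
  }
  pr <- ppo_unpack(par, Jm1, ncol(Xp), ncol(Xn))
  ll <- -ppo_negll(par, Xp, Xn, y, Jm1, ridge = 0)

  # monotonicity of eta_j in j depends on theta_j + tau_j' x_non only
  monotone_ok <- all(diff(pr$theta) >= 0)
  if (ncol(Xn) > 0 && nrow(Xn) > 0) {
    xs <- unique(Xn)
    etas <- matrix(pr$theta, nrow(xs), Jm1, byrow = TRUE) + xs %*% t(pr$tau)
    monotone_ok <- monotone_ok && all(apply(etas, 1, function(e) all(diff(e) >= 0)))
  }
  if (!monotone_ok) {
    warning("fitted cumulative probabilities cross at some training pattern; ",
            "predictions will floor and renormalize (monotone_ok = FALSE)")
  }
  H <- tryCatch(stats::optimHess(par, ppo_negll, ppo_negll_grad, Xp = Xp,
                                 Xn = Xn, y = y, Jm1 = Jm1, ridge = opts$ridge),
                error = function(e) NULL)
  V <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL) else NULL
  nms <- ppo_coef_names(Jm1, partition)
  if (!is.null(V)) dimnames(V) <- list(nms, nms)

  structure(list(
    theta = stats::setNames(pr$theta, paste0("theta_", seq_len(Jm1))),
    beta = stats::setNames(pr$beta, partition$parallel),
    tau = structure(pr$tau, dimnames = list(paste0("j", seq_len(Jm1)),
                                            partition$nonparallel)),
    partition = partition, levels = as.integer(levels_used),
    log_likelihood = ll, converged = converged, monotone_ok = monotone_ok,
    n_train = n, npar = npar, options = opts, vcov = V, grad_norm = grad_norm
  ), class = "ppo_fit")
}

ppo_coef_names <- function(Jm1, partition) {
  taunames <- if (length(partition$nonparallel) == 0) character(0)
  else as.vector(outer(paste0("j", seq_len(Jm1)), partition$nonparallel,
                       function(a, b) paste0(b, ":", a)))
  c(paste0("theta_", seq_len(Jm1)), partition$parallel, taunames)
}

#' Cumulative logit of a fitted model
#'
#' Returns `eta_j(x) = theta_j + beta' x_par + tau_j' x_nonpar`, the linear
#' predictor of `logit P(Y <= level_j | x)`.
#'
#' @param model A `ppo_fit`.
#' @param newdata Data frame (or single named vector) of predictor values.
#' @param j Cut-point index in `1..(J-1)` (1..4 for the full scale).
#' @return Numeric vector, one value per row of `newdata`.
#' @export
cumulative_logit <- function(model, newdata, j) {
  stopifnot(inherits(model, "ppo_fit"))
  Jm1 <- length(model$theta)
  if (!(length(j) == 1 && j %in% seq_len(Jm1))) {
    stop("cut index j must be a single integer in 1..", Jm1)
  }
  eta_full(model, newdata)[, j]
}

eta_full <- function(model, newdata) {
  if (!is.data.frame(newdata)) newdata <- as.data.frame(as.list(newdata))
  des <- ppo_design(newdata, model$partition)
  eta <- ppo_eta_mat(unname(model$theta), unname(model$beta),
                     unname(model$tau), des$Xp, des$Xn)
  if (any(!is.finite(eta))) stop("non-finite cumulative logit")
  eta
}

#' Category probabilities under a model
#'
#' Generic contract shared by the ordinal causality-assessment model and
#' the baseline classifiers: an `n x 5` matrix of probabilities over the
#' causality categories 1..5, rows summing to one.
#'
#' @param object A fitted model.
#' @param newdata Report table (or single predictor vector).
#' @param ... Method-specific arguments.
#' @return Numeric matrix with `nrow(newdata)` rows and columns `"1".."5"`.
#' @export
category_probabilities <- function(object, newdata, ...) {
  UseMethod("category_probabilities")
}

#' @describeIn category_probabilities `P(Y = j) = F(eta_j) - F(eta_{j-1})`
#'   with `F` the standard logistic CDF, `F(eta_0) = 0`, `P(Y <= J) = 1`.
#'   If crossing cumulative curves make any difference negative, the entry
#'   is floored at 1e-12, the row renormalized, and the number of affected
#'   rows reported in attribute `"n_floored"` with a warning.
#' @export
category_probabilities.ppo_fit <- function(object, newdata, ...) {
  eta <- eta_full(object, newdata)
  G <- cbind(0, stats::plogis(eta), 1)
  P <- G[, -1, drop = FALSE] - G[, -ncol(G), drop = FALSE]
  n_floored <- sum(apply(P < 0, 1, any))
  if (n_floored > 0) {
    warning(n_floored, " row(s) had negative category probabilities; ",
            "floored and renormalized")
    P <- pmax(P, PROB_FLOOR)
    P <- P / rowSums(P)
  }
  out <- matrix(0, nrow(P), 5, dimnames = list(NULL, as.character(1:5)))
  out[, as.character(object$levels)] <- P
  attr(out, "n_floored") <- n_floored
  out
}

#' Log-likelihood of labeled reports under a model
#'
#' `sum_i log P(Y = y_i | x_i)`; an empty table gives 0.
#'
#' @param model A `ppo_fit`.
#' @param data Labeled report table.
#' @param label Label column name.
#' @param strict If `TRUE` (default) a record whose fitted category
#'   probability is not positive raises an error naming the record;
#'   otherwise probabilities are floored at 1e-12.
#' @return A single number, always `<= 0` up to the floor.
#' @export
ppo_loglik <- function(model, data, label = "prov_assess", strict = TRUE) {
  if (nrow(data) == 0) return(0)
  y <- as.integer(data[[label]])
  if (any(!(y %in% 1:5))) stop("labels must be in 1..5")
  eta <- eta_full(model, data)
  G <- cbind(0, stats::plogis(eta), 1)
  P5 <- matrix(0, nrow(G), 5)
  P5[, model$levels] <- G[, -1, drop = FALSE] - G[, -ncol(G), drop = FALSE]
  p <- P5[cbind(seq_along(y), y)]
  if (any(p <= 0)) {
    if (strict) {
      stop("non-positive fitted probability for record ", which(p <= 0)[1])
    }
    p <- pmax(p, PROB_FLOOR)
  }
  sum(log(p))
}

#' Predict the causality category
#'
#' Argmax over [category_probabilities()]; ties are broken toward the
#' lower (less certain) category.
#'
#' @inheritParams category_probabilities
#' @param model A fitted model exposing category probabilities.
#' @return Integer vector of categories in 1..5.
#' @export
predict_category <- function(model, newdata) {
  P <- category_probabilities(model, newdata)
  as.integer(max.col(P, ties.method = "first"))
}

#' Likelihood-ratio test of the parallel assumption for one variable
#'
#' Compares the all-parallel (proportional-odds) fit with the fit freeing
#' `variable` across the cumulative logits.  For the 5-category outcome the
#' alternative adds 4 threshold-specific coefficients and removes 1 shared
#' one, so the statistic is referred to a chi-square with 3 degrees of
#' freedom.
#'
#' @inheritParams fit_ppo
#' @param variable Predictor name to test.
#' @param vars Predictors used by both fits (default all 11).
#' @return A list with `statistic`, `df`, `p_value`, `reliable` (FALSE if
#'   either fit failed to converge) and `variable`.
#' @export
lr_test_parallel <- function(data, variable, label = "prov_assess",
                             opts = fit_options(), vars = predictor_names()) {
  if (!variable %in% vars) stop("unknown predictor: ", variable)
  null_fit <- fit_ppo(data, model_partition(parallel = vars), label, opts)
  alt_fit <- fit_ppo(data,
                     model_partition(parallel = setdiff(vars, variable),
                                     nonparallel = variable),
                     label, opts)
  stat <- 2 * (alt_fit$log_likelihood - null_fit$log_likelihood)
  df <- length(null_fit$levels) - 2L
  reliable <- null_fit$converged && alt_fit$converged
  if (!reliable) warning("a component fit did not converge; test unreliable")
  list(statistic = stat, df = df,
       p_value = stats::pchisq(max(stat, 0), df, lower.tail = FALSE),
       reliable = reliable, variable = variable)
}

#' Select the non-parallel variable set by per-variable score
#'
#' Runs [lr_test_parallel()] for each predictor against the all-parallel
#' null; variables with `p < alpha` form the non-parallel set.
#' Deterministic given the data.
#'
#' @inheritParams lr_test_parallel
#' @param alpha Significance level in (0, 1); `alpha = 0` keeps every
#'   variable parallel.
#' @return A [model_partition()]; per-variable p-values are attached as
#'   attribute `"p_values"`.
#' @export
select_partition <- function(data, alpha = 0.05, label = "prov_assess",
                             opts = fit_options(), vars = predictor_names()) {
  if (alpha < 0 || alpha >= 1) stop("alpha must be in [0, 1)")
  pvals <- vapply(vars, function(v) {
    lr_test_parallel(data, v, label, opts, vars)$p_value
  }, numeric(1))
  nonpar <- vars[pvals < alpha]
  out <- model_partition(parallel = setdiff(vars, nonpar), nonparallel = nonpar)
  attr(out, "p_values") <- pvals
  out
}

#' @export
logLik.ppo_fit <- function(object, ...) {
  structure(object$log_likelihood, df = object$npar, nobs = object$n_train,
            class = "logLik")
}

#' @export
coef.ppo_fit <- function(object, ...) {
  stats::setNames(c(unname(object$theta), unname(object$beta),
                    as.vector(unname(object$tau))),
                  ppo_coef_names(length(object$theta), object$partition))
}

#' @export
vcov.ppo_fit <- function(object, ...) object$vcov

#' @export
print.ppo_fit <- function(x, ...) {
  cat("Partial proportional-odds causality-assessment model\n")
  cat(sprintf("  categories: %s   n_train: %d   logLik: %s\n",
              paste(x$levels, collapse = ","), x$n_train,
              format(x$log_likelihood, digits = 6)))
  cat(sprintf("  parallel vars: %d   non-parallel vars: %d   converged: %s   monotone: %s\n",
              length(x$partition$parallel), length(x$partition$nonparallel),
              x$converged, x$monotone_ok))
  cat("  cut points:", format(unname(x$theta), digits = 4), "\n")
  if (length(x$beta) > 0) {
    cat("  beta (positive -> lower categories):\n")
    print(round(x$beta, 4))
  }
  if (ncol(x$tau) > 0) {
    cat("  tau (per cut point):\n")
    print(round(x$tau, 4))
  }
  invisible(x)
}
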
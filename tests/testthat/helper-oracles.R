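# Independent oracles used across the suite.  These deliberately share no
# code with the package internals: plain loops, explicit case splits and
# generic optimizers.

# Loop-based log-likelihood of the 2-predictor partial proportional-odds
# model (one parallel, one threshold-specific variable), probabilities
# floored at 1e-12 like the package objective.
naive_ppo_ll <- function(par, x1, x2, y) {
  theta <- par[1:4]; beta <- par[5]; tau <- par[6:9]
  ll <- 0
  for (i in seq_along(y)) {
    eta <- theta + beta * x1[i] + tau * x2[i]
    cum <- c(0, 1 / (1 + exp(-eta)), 1)
    p <- cum[y[i] + 1] - cum[y[i]]
    ll <- ll + log(max(p, 1e-12))
  }
  ll
}

# Generic-optimizer oracle for the maximized log-likelihood: multi-start
# Nelder-Mead followed by a numeric-gradient BFGS polish.
oracle_max_ll <- function(x1, x2, y) {
  cf <- cumsum(tabulate(y, 5)) / length(y)
  th0 <- log(cf[1:4] / (1 - cf[1:4]))
  starts <- list(c(th0, rep(0, 5)),
                 c(th0, rep(0.5, 5)),
                 c(th0, rep(-0.5, 5)))
  best <- -Inf
  for (s in starts) {
    r1 <- stats::optim(s, function(p) -naive_ppo_ll(p, x1, x2, y),
                       method = "Nelder-Mead",
                       control = list(maxit = 50000, reltol = 1e-14))
    r2 <- stats::optim(r1$par, function(p) -naive_ppo_ll(p, x1, x2, y),
                       method = "BFGS",
                       control = list(maxit = 2000, reltol = 1e-14))
    best <- max(best, -r1$value, -r2$value)
  }
  best
}

# Draw a small labeled table with 2 predictors where every outcome
# category occurs at least twice (regular MLE).
small_ppo_dataset <- function(seed, n = 50) {
  v <- predictor_names()[1:2]
  repeat {
    set.seed(seed)
    x1 <- rbinom(n, 1, 0.5); x2 <- rbinom(n, 1, 0.5)
    theta <- qlogis((1:4) / 5)
    tau <- c(-0.6, -0.2, 0.2, 0.6)
    eta <- outer(0.7 * x1, rep(1, 4)) + outer(x2, tau) +
      matrix(theta, n, 4, byrow = TRUE)
    cum <- cbind(0, 1 / (1 + exp(-eta)), 1)
    p <- cum[, -1, drop = FALSE] - cum[, -6, drop = FALSE]
    u <- runif(n)
    y <- rowSums(u > t(apply(p, 1, cumsum))) + 1L
    if (all(tabulate(y, 5) >= 2)) break
    seed <- seed + 1000
  }
  tab <- tibble::tibble(!!v[1] := as.integer(x1), !!v[2] := as.integer(x2),
                        prov_assess = as.integer(y))
  list(table = tab, x1 = x1, x2 = x2, y = y, vars = v)
}

# O(n^2) concordant-pair AUC with ties counted one half.
pairwise_auc <- function(score, pos) {
  ps <- score[pos]; ns <- score[!pos]
  if (length(ps) == 0 || length(ns) == 0) return(NA_real_)
  tot <- 0
  for (a in ps) tot <- tot + sum(a > ns) + 0.5 * sum(a == ns)
  tot / (length(ps) * length(ns))
}

# Explicit scalar case split for the warning signal.
signal_oracle_s <- function(y, y0, serious, variant) {
  side <- function(v) if (v > 3) 1 else if (v < 3) -1 else 0
  d <- if (side(y) * side(y0) > 0) abs(y - y0)
       else if (side(y) == 0 || side(y0) == 0) y + y0 - 6
       else -abs(y - y0)
  r <- if (serious) 4 else 1
  if (variant == "eq8_literal") r * (d + 1)
  else if (d >= 0) r * (d + 1) else r * d
}

# Simulate a labeled table from an explicit low-dimensional true model,
# fit-ready (no missing labels).
sim_small_model <- function(n, seed, beta1 = 0.6, beta2 = -0.4,
                            tau = NULL) {
  v <- predictor_names()[1:2]
  true <- if (is.null(tau)) {
    ppo_model(qlogis((1:4) / 5),
              beta = setNames(c(beta1, beta2), v))
  } else {
    ppo_model(qlogis((1:4) / 5),
              beta = setNames(beta2, v[2]),
              tau = matrix(tau, 4, 1, dimnames = list(NULL, v[1])))
  }
  prev <- setNames(rep(0.5, 11), predictor_names())
  cfg <- sim_config(n = n, prevalence = prev, true_model = true,
                    missing_prov_rate = 0, seed = seed)
  simulate_reports(cfg)
}
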
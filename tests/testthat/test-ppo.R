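v1 <- predictor_names()[1]
v2 <- predictor_names()[2]

test_that("cumulative logits follow the stated parameterization", {
  zero <- ppo_model(theta = rep(0, 4), beta = setNames(0, v1))
  x <- tibble::tibble(!!v1 := c(0L, 1L))
  for (j in 1:4) expect_equal(cumulative_logit(zero, x, j), c(0, 0))

  hand <- ppo_model(theta = c(-1, 0, 1, 2), beta = setNames(0.5, v1))
  expect_equal(cumulative_logit(hand, tibble::tibble(!!v1 := 1L), 3), 1.5)
  expect_error(cumulative_logit(hand, x, 5), "cut index")

  # parallel model: logit differences do not depend on x
  po <- ppo_model(theta = c(-2, -0.5, 0.4, 1.7),
                  beta = setNames(c(0.8, -1.1), c(v1, v2)))
  x <- tibble::tibble(!!v1 := c(0L, 1L, 1L), !!v2 := c(0L, 0L, 1L))
  for (j in 1:3) {
    expect_equal(cumulative_logit(po, x, j + 1) - cumulative_logit(po, x, j),
                 rep(po$theta[[j + 1]] - po$theta[[j]], 3))
  }
})

test_that("category probabilities are logistic-CDF differences summing to one", {
  unif <- ppo_model(theta = qlogis((1:4) / 5))
  p <- category_probabilities(unif, tibble::tibble(.rows = 1))
  expect_equal(as.numeric(p), rep(0.2, 5), tolerance = 1e-12)

  hand <- ppo_model(theta = c(0, 1, 2, 3))
  p2 <- category_probabilities(hand, tibble::tibble(.rows = 1))
  expect_equal(as.numeric(p2), c(0.5000, 0.2311, 0.1497, 0.0718, 0.0474),
               tolerance = 1e-3)

  set.seed(5)
  for (rep in 1:20) {
    m <- ppo_model(theta = sort(rnorm(4, sd = 2)),
                   beta = setNames(rnorm(2), c(v1, v2)))
    x <- tibble::tibble(!!v1 := rbinom(10, 1, 0.5), !!v2 := rbinom(10, 1, 0.5))
    P <- category_probabilities(m, x)
    expect_equal(rowSums(P), rep(1, 10), tolerance = 1e-12)
    expect_true(all(P >= 0))
  }
})

test_that("crossing cumulative curves are floored, renormalized and counted", {
  m <- ppo_model(theta = c(-1, 0, 1, 2),
                 tau = matrix(c(3, -3, 3, -3), 4, 1,
                              dimnames = list(NULL, v1)))
  x <- tibble::tibble(!!v1 := c(0L, 1L))
  expect_warning(P <- category_probabilities(m, x), "floored")
  expect_equal(attr(P, "n_floored"), 1)
  expect_equal(rowSums(P), c(1, 1), tolerance = 1e-9)
  expect_true(all(P >= 0))
})

test_that("log-likelihood matches hand-computed values", {
  unif <- ppo_model(theta = qlogis((1:4) / 5))
  tab <- tibble::tibble(prov_assess = rep(1:5, 2))
  expect_equal(ppo_loglik(unif, tab), 10 * log(0.2))
  expect_equal(ppo_loglik(unif, tab[0, ]), 0)

  hand <- ppo_model(theta = c(0, 1, 2, 3))
  two <- tibble::tibble(prov_assess = c(1L, 5L))
  expect_equal(ppo_loglik(hand, two),
               log(0.5) + log(1 - plogis(3)), tolerance = 1e-12)
})

test_that("intercept-only fit equals the closed-form multinomial MLE", {
  set.seed(3)
  y <- sample(1:5, 400, replace = TRUE, prob = c(0.1, 0.15, 0.3, 0.25, 0.2))
  tab <- tibble::tibble(prov_assess = as.integer(y))
  fit <- fit_ppo(tab, model_partition(parallel = character()))
  emp <- cumsum(tabulate(y, 5))[1:4] / length(y)
  expect_equal(unname(plogis(fit$theta)), emp, tolerance = 1e-8)
})

test_that("the proportional-odds special case agrees with an established implementation", {
  tab <- sim_small_model(n = 1500, seed = 21)
  part <- model_partition(parallel = c(v1, v2))
  fit <- fit_ppo(tab, part)
  df <- data.frame(y = factor(tab$prov_assess, levels = 1:5, ordered = TRUE),
                   x1 = tab[[v1]], x2 = tab[[v2]])
  ref <- MASS::polr(y ~ x1 + x2, data = df, method = "logistic")
  expect_equal(fit$log_likelihood, as.numeric(stats::logLik(ref)),
               tolerance = 1e-6)
  # reference uses logit P(Y<=j) = zeta_j - eta: slopes flip sign
  expect_equal(unname(fit$beta), unname(-stats::coef(ref)), tolerance = 1e-4)
  expect_equal(unname(fit$theta), unname(ref$zeta), tolerance = 1e-4)
})

test_that("freeing a variable never lowers the maximized log-likelihood", {
  tab <- sim_small_model(n = 800, seed = 31, tau = c(-0.6, -0.2, 0.2, 0.6))
  po <- fit_ppo(tab, model_partition(parallel = c(v1, v2)))
  ppo <- fit_ppo(tab, model_partition(parallel = v2, nonparallel = v1))
  expect_gte(ppo$log_likelihood, po$log_likelihood - 1e-8)
  # and with no freed variable the two coincide by construction
  expect_equal(fit_ppo(tab, model_partition(parallel = c(v1, v2)))$log_likelihood,
               po$log_likelihood)
})

test_that("fitting is deterministic given data and options", {
  tab <- sim_small_model(n = 600, seed = 41)
  part <- model_partition(parallel = v2, nonparallel = v1)
  f1 <- fit_ppo(tab, part)
  f2 <- fit_ppo(tab, part)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$log_likelihood, f2$log_likelihood)
})

test_that("argmax prediction breaks ties toward the lower category", {
  # theta = (0, 40, 41, 42) gives exactly (0.5, 0.5, 0, 0, 0)
  tie <- ppo_model(theta = c(0, 40, 41, 42))
  expect_equal(predict_category(tie, tibble::tibble(.rows = 1)), 1L)
  hand <- ppo_model(theta = c(0, 1, 2, 3))
  expect_equal(predict_category(hand, tibble::tibble(.rows = 1)), 1L)
  high <- ppo_model(theta = c(-9, -8, -7, -6))   # mass on category 5
  expect_equal(predict_category(high, tibble::tibble(.rows = 1)), 5L)
})

test_that("empty training categories follow the declared policy", {
  tab <- sim_small_model(n = 500, seed = 51)
  tab <- tab[tab$prov_assess != 1, ]
  part <- model_partition(parallel = c(v1, v2))
  expect_error(fit_ppo(tab, part), "absent.*1")
  fit <- fit_ppo(tab, part, opts = fit_options(empty_category = "merge"))
  expect_equal(fit$levels, 2:5)
  P <- category_probabilities(fit, tab[1:5, ])
  expect_true(all(P[, "1"] == 0))
  expect_true(all(predict_category(fit, tab[1:10, ]) %in% 2:5))
})

test_that("estimated coefficients approach the truth as n grows", {
  truth <- c(0.6, -0.4)
  reps <- 30
  # common random numbers across sample sizes to correlate the bias curves
  bias_at <- function(n) {
    err <- vapply(seq_len(reps), function(r) {
      tab <- sim_small_model(n = n, seed = 5000 + r)
      fit <- fit_ppo(tab, model_partition(parallel = c(v1, v2)))
      mean(abs(unname(fit$beta) - truth))
    }, numeric(1))
    mean(err)
  }
  b <- vapply(c(400, 1600, 6400), bias_at, numeric(1))
  expect_lt(b[2], b[1])
  expect_lt(b[3], b[2])
})
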
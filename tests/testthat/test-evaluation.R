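rand_probs <- function(n, seed) {
  set.seed(seed)
  P <- matrix(runif(n * 5), n, 5, dimnames = list(NULL, 1:5))
  P / rowSums(P)
}

test_that("accuracy counts exact matches", {
  expect_equal(accuracy(c(3, 4, 4, 5), c(3, 3, 4, 5)), 0.75)
  expect_equal(accuracy(1:5, 1:5), 1.0)
  expect_equal(accuracy(rep(1, 4), rep(2, 4)), 0.0)
  expect_error(accuracy(1:3, 1:4), "length mismatch")
})

test_that("per-class F1 follows precision/recall arithmetic", {
  f <- f1_per_class(c(3, 4, 4), c(3, 3, 4))
  expect_equal(unname(f[["3"]]), 2 / 3)
  expect_equal(unname(f[["4"]]), 2 / 3)
  perfect <- f1_per_class(c(2, 3, 5), c(2, 3, 5))
  expect_equal(unname(perfect[c("2", "3", "5")]), c(1, 1, 1))
  # never predicted, never true -> 0 by convention
  expect_equal(unname(perfect[["1"]]), 0)
})

test_that("one-vs-rest ROC endpoints, monotonicity and degenerate cases", {
  P <- rand_probs(100, 1)
  truth <- sample(1:5, 100, replace = TRUE)
  r <- roc_ovr(P, truth, 3)
  expect_equal(r$curve[1, ], c(fpr = 0, tpr = 0))
  expect_equal(r$curve[nrow(r$curve), ], c(fpr = 1, tpr = 1))
  expect_true(all(diff(r$curve[, 1]) >= 0))
  expect_true(all(diff(r$curve[, 2]) >= 0))

  sep <- matrix(c(0.9, 0.8, 0.1, 0.2), 4, 1)
  colnames(sep) <- "5"
  P2 <- cbind("1" = 1 - sep[, 1], "2" = 0, "3" = 0, "4" = 0, "5" = sep[, 1])
  expect_equal(roc_ovr(P2, c(5, 5, 1, 1), 5)$auc, 1.0)

  Pc <- matrix(0.2, 6, 5, dimnames = list(NULL, 1:5))
  expect_equal(roc_ovr(Pc, c(1, 2, 3, 4, 5, 1), 2)$auc, 0.5)

  expect_true(is.na(roc_ovr(Pc, rep(1, 6), 4)$auc))  # class absent
})

test_that("sweep AUC equals the pairwise concordance oracle", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(5:200, 1)
    score <- round(runif(n), sample(1:2, 1))   # induce ties
    pos <- runif(n) < 0.4
    if (!any(pos) || all(pos)) next
    P <- cbind("1" = 1 - score, "2" = 0, "3" = 0, "4" = 0, "5" = score)
    truth <- ifelse(pos, 5L, 1L)
    expect_equal(roc_ovr(P, truth, 5)$auc, pairwise_auc(score, pos),
                 tolerance = 1e-12)
  }
})

test_that("sweep AUC agrees with an established ROC implementation", {
  set.seed(42)
  score <- round(runif(80), 2)
  pos <- runif(80) < 0.5
  P <- cbind("1" = 1 - score, "2" = 0, "3" = 0, "4" = 0, "5" = score)
  truth <- ifelse(pos, 5L, 1L)
  ref <- suppressMessages(pROC::auc(pROC::roc(as.integer(pos), score,
                                              direction = "<", quiet = TRUE)))
  expect_equal(roc_ovr(P, truth, 5)$auc, as.numeric(ref), tolerance = 1e-12)
})

test_that("macro AUC is invariant to class relabeling; micro to row order", {
  P <- rand_probs(150, 3)
  set.seed(3); truth <- sample(1:5, 150, replace = TRUE)
  perm <- c(3, 1, 5, 2, 4)
  P2 <- P[, as.character(order(perm))]
  colnames(P2) <- as.character(1:5)
  truth2 <- perm[truth]
  expect_equal(auc_macro(P, truth), auc_macro(P2, truth2), tolerance = 1e-12)

  ord <- sample(150)
  expect_equal(auc_micro(P, truth), auc_micro(P[ord, ], truth[ord]),
               tolerance = 1e-12)
})

test_that("a perfect classifier scores 1 on every aggregate", {
  truth <- rep(1:5, each = 4)
  P <- matrix(0.001, 20, 5, dimnames = list(NULL, 1:5))
  P[cbind(1:20, truth)] <- 1 - 4 * 0.001
  expect_equal(accuracy(max.col(P), truth), 1.0)
  expect_equal(auc_macro(P, truth), 1.0)
  expect_equal(auc_micro(P, truth), 1.0)
})

test_that("evaluate_model assembles consistent reports deterministically", {
  tab <- sim_small_model(n = 500, seed = 141)
  fit <- fit_ppo(tab, model_partition(parallel = predictor_names()[1:2]))
  ev1 <- evaluate_model(fit, tab)
  ev2 <- evaluate_model(fit, tab)
  expect_identical(ev1, ev2)
  expect_gte(ev1$accuracy, max(ev1$class_counts) / ev1$n_test - 0.05)
  expect_true(all(ev1$auc_by_class >= 0 & ev1$auc_by_class <= 1, na.rm = TRUE))
  expect_equal(sum(ev1$class_counts), ev1$n_test)
  pts <- roc_points(ev1)
  expect_true(all(pts$fpr >= 0 & pts$fpr <= 1))

  # identical probability outputs => identical reports
  path <- withr::local_tempfile(fileext = ".json")
  write_model(fit, path)
  clone <- read_model(path)
  expect_equal(evaluate_model(clone, tab)[c("accuracy", "auc_by_class",
                                            "auc_macro", "auc_micro")],
               ev1[c("accuracy", "auc_by_class", "auc_macro", "auc_micro")])
})
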
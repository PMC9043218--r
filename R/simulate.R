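# Synthetic ADR report generator -----------------------------------------
#
# Emulates the statistical structure the assessment pipeline assumes:
# independent Bernoulli Boolean predictors, an ordinal causality category
# drawn from a partial proportional-odds process, a serious-ADE flag
# derived as the OR of the six severity items, reporter-side assessments
# equal to the true category plus clamped additive noise, and a
# provincial expert assessment observed for only part of the reports.

DEFAULT_PREVALENCE <- c(
  causality_assessment_1 = 0.70, causality_assessment_2 = 0.55,
  causality_assessment_3 = 0.45, causality_assessment_4 = 0.10,
  causality_assessment_5 = 0.20,
  severity_assessment_1 = 0.02, severity_assessment_2 = 0.01,
  severity_assessment_3 = 0.03, severity_assessment_4 = 0.04,
  severity_assessment_5 = 0.12, severity_assessment_6 = 0.08)

# Frozen one-time draw (standard normal scaled by 0.8) for the parallel
# slopes of the default true model.
DEFAULT_BETA <- c(
  causality_assessment_1 = 1.097, causality_assessment_2 = -0.452,
  causality_assessment_3 = 0.291, causality_assessment_4 = 0.506,
  severity_assessment_1 = 0.323, severity_assessment_2 = -0.085,
  severity_assessment_3 = 1.209, severity_assessment_4 = -0.076,
  severity_assessment_5 = 1.615, severity_assessment_6 = -0.050)

#' Default true model of the synthetic generator
#'
#' Cut points at `logit(j/5)` (so the outcome is uniform over 1..5 at zero
#' covariates), ten parallel slopes frozen from a one-time standard-normal
#' draw scaled by 0.8, and one non-parallel variable
#' (`causality_assessment_5`, "can be explained by other factors") with
#' threshold-specific coefficients `(-0.9, -0.3, 0.3, 0.9)`.  The spread of
#' 1.8 across cut points is a clear parallel-assumption violation while
#' keeping all cumulative curves monotone for every covariate pattern.
#'
#' @return A `ppo_fit` object (see [ppo_model()]).
#' @export
default_true_model <- function() {
  tau <- matrix(c(-0.9, -0.3, 0.3, 0.9), 4, 1,
                dimnames = list(NULL, "causality_assessment_5"))
  ppo_model(theta = stats::qlogis((1:4) / 5), beta = DEFAULT_BETA, tau = tau)
}

#' Configuration of the synthetic report generator
#'
#' @param n Number of reports.
#' @param prevalence Named 11-vector of Bernoulli probabilities for the
#'   predictor items.
#' @param true_model `ppo_fit` object generating the true causality
#'   category (see [default_true_model()]).
#' @param reporter_noise Distribution over offsets `-2..2` (named numeric,
#'   summing to 1) added independently to the true category for the
#'   reporter, institute and municipal assessments, then clamped to 1..5.
#' @param missing_prov_rate Probability that the provincial assessment is
#'   masked to `-1` (unreviewed report).
#' @param suspect_rate,new_ade_rate,gender_rate Bernoulli rates of the
#'   metadata flags.
#' @param seed Integer seed; generation is fully reproducible from it.
#' @return A `sim_config` object.
#' @export
sim_config <- function(n = 5000,
                       prevalence = DEFAULT_PREVALENCE,
                       true_model = default_true_model(),
                       reporter_noise = c("-2" = 0.05, "-1" = 0.15,
                                          "0" = 0.60, "1" = 0.15, "2" = 0.05),
                       missing_prov_rate = 0.2,
                       suspect_rate = 0.8,
                       new_ade_rate = 0.1,
                       gender_rate = 0.5,
                       seed = 1L) {
  stopifnot(n >= 0, inherits(true_model, "ppo_fit"))
  if (length(prevalence) != 11 || is.null(names(prevalence)) ||
      !setequal(names(prevalence), predictor_names())) {
    stop("prevalence must be named over the 11 predictor columns")
  }
  probs <- c(prevalence, missing_prov_rate, suspect_rate, new_ade_rate,
             gender_rate)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  if (!setequal(names(reporter_noise), as.character(-2:2)) ||
      abs(sum(reporter_noise) - 1) > 1e-12 || any(reporter_noise < 0)) {
    stop("reporter_noise must be a distribution over offsets -2..2")
  }
  structure(list(n = as.integer(n),
                 prevalence = prevalence[predictor_names()],
                 true_model = true_model,
                 reporter_noise = reporter_noise[as.character(-2:2)],
                 missing_prov_rate = missing_prov_rate,
                 suspect_rate = suspect_rate, new_ade_rate = new_ade_rate,
                 gender_rate = gender_rate, seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a synthetic labeled report table
#'
#' Predictors are independent Bernoulli draws; the true causality category
#' is drawn from [category_probabilities()] of the configured true model;
#' `prov_assess` equals the true category, masked to `-1` at the
#' configured rate; the reporter, institute and municipal assessments are
#' the true category plus independent clamped noise offsets;
#' `serious_ade` is the OR of the six severity items.  Bit-identical
#' tables for identical configurations.
#'
#' @param config A [sim_config()].
#' @return Report table (tibble) passing [validate_reports()] with zero
#'   violations; the true category is kept in column `true_category`.
#' @export
simulate_reports <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n
  X <- vapply(predictor_names(),
              function(v) stats::rbinom(n, 1L, config$prevalence[[v]]),
              integer(n))
  if (n == 1) X <- matrix(X, 1, dimnames = list(NULL, predictor_names()))
  if (n == 0) X <- matrix(integer(0), 0, 11, dimnames = list(NULL, predictor_names()))
  Xdf <- tibble::as_tibble(as.data.frame(X))

  P <- raw_category_probs(config$true_model, Xdf)
  if (any(P < 0)) {
    bad <- which(apply(P < 0, 1, any))[1]
    stop("degenerate true model: non-monotone cumulative probabilities at x = (",
         paste(X[bad, ], collapse = ","), ") [row ", bad, "]")
  }
  CP <- P
  for (j in 2:5) CP[, j] <- CP[, j - 1] + P[, j]
  y <- as.integer(rowSums(stats::runif(n) > CP) + 1L)

  offsets <- as.integer(names(config$reporter_noise))
  noisy <- function() {
    off <- sample(offsets, n, replace = TRUE, prob = config$reporter_noise)
    pmin(pmax(y + off, 1L), 5L)
  }
  r_assess <- noisy(); ri_assess <- noisy(); muni_assess <- noisy()
  prov_assess <- y
  prov_assess[stats::runif(n) < config$missing_prov_rate] <- -1L

  out <- Xdf
  out$new_ade <- stats::rbinom(n, 1L, config$new_ade_rate)
  out$serious_ade <- as.integer(rowSums(X[, SEVERITY_COLS, drop = FALSE]) > 0)
  out$gender <- stats::rbinom(n, 1L, config$gender_rate)
  out$suspect <- stats::rbinom(n, 1L, config$suspect_rate)
  out$r_assess <- r_assess
  out$ri_assess <- ri_assess
  out$muni_assess <- muni_assess
  out$prov_assess <- prov_assess
  out$true_category <- y
  out
}

# Category probabilities without the crossing floor, for generation checks.
raw_category_probs <- function(model, newdata) {
  eta <- eta_full(model, newdata)
  G <- cbind(0, stats::plogis(eta), 1)
  P <- G[, -1, drop = FALSE] - G[, -ncol(G), drop = FALSE]
  out <- matrix(0, nrow(P), 5, dimnames = list(NULL, as.character(1:5)))
  out[, as.character(model$levels)] <- P
  out
}

#' Analytic marginal category distribution of a configuration
#'
#' Exact marginal `P(Y = j)` under the generator, by exhaustive summation
#' over all 2^11 covariate patterns weighted by their Bernoulli
#' probabilities.  Used as an oracle against empirical frequencies.
#'
#' @param config A [sim_config()].
#' @return Numeric 5-vector summing to 1.
#' @export
marginal_category_probs <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  patterns <- as.matrix(expand.grid(rep(list(0:1), 11)))
  colnames(patterns) <- predictor_names()
  pv <- config$prevalence
  w <- apply(patterns, 1, function(x) prod(ifelse(x == 1, pv, 1 - pv)))
  P <- raw_category_probs(config$true_model, as.data.frame(patterns))
  drop(crossprod(P, w))
}

#' Deterministic staircase model for fixtures and examples
#'
#' Proportional-odds model whose prediction is fully determined by the
#' first four causality items: with `k` of them set, the predicted
#' category is `5 - k` (strong slopes, widely separated cut points).
#' Handy for building tables whose model assessment is known by
#' construction.
#'
#' @return A `ppo_fit` object.
#' @export
fixture_model <- function() {
  beta <- stats::setNames(c(rep(5, 4), rep(0, 7)),
                          c(CAUSALITY_COLS[1:4], CAUSALITY_COLS[5], SEVERITY_COLS))
  ppo_model(theta = c(-17.5, -12.5, -7.5, -2.5), beta = beta)
}

fixture_row <- function(k = 0L, y0 = 1L, serious = FALSE, suspect = 1L,
                        r = y0, muni = 3L, prov = 4L, new_ade = 0L,
                        gender = 0L) {
  row <- stats::setNames(as.list(rep(0L, length(REQUIRED_COLS))), REQUIRED_COLS)
  if (k > 0) for (v in CAUSALITY_COLS[seq_len(k)]) row[[v]] <- 1L
  if (serious) row[["severity_assessment_5"]] <- 1L
  row$serious_ade <- as.integer(serious)
  row$suspect <- as.integer(suspect)
  row$new_ade <- as.integer(new_ade)
  row$gender <- as.integer(gender)
  row$r_assess <- as.integer(r)
  row$ri_assess <- as.integer(y0)
  row$muni_assess <- as.integer(muni)
  row$prov_assess <- as.integer(prov)
  tibble::as_tibble(row)
}

#' Named deterministic test fixtures
#'
#' Small tables with known structure, built in code:
#' \describe{
#'   \item{`worked_examples`}{Nine serious suspect-drug reports mirroring
#'     the reference worked examples: eight whose model assessment is 4 and
#'     one whose assessment is 5, all with institute assessment 1, so the
#'     default-variant signal `s` is -12 and -16 respectively (predictions
#'     under [fixture_model()]).}
#'   \item{`planted_opposite`}{1000 rows, exactly 7 of which (attribute
#'     `"planted"`) satisfy the `opposite_assessments` preset after
#'     extension with [fixture_model()].}
#'   \item{`all_branches`}{25 rows covering every assessment pair
#'     `(Y, Y0)` in `{1..5}^2`: the model prediction is `Y` by
#'     construction and `ri_assess = Y0`.}
#' }
#'
#' @param name Fixture name.
#' @return A report table; fixtures are deterministic.
#' @export
make_fixture <- function(name = c("worked_examples", "planted_opposite",
                                  "all_branches")) {
  name <- match.arg(name)
  if (name == "worked_examples") {
    rows <- c(lapply(1:8, function(i) {
      fixture_row(k = 1L, y0 = 1L, serious = TRUE, r = 1L, muni = 3L, prov = 4L,
                  gender = i %% 2L)
    }), list(fixture_row(k = 0L, y0 = 1L, serious = TRUE, r = 1L, muni = 3L,
                         prov = 4L)))
    out <- do.call(rbind, rows)
    out$drug_name <- sprintf("drug_%02d", seq_len(nrow(out)))
    return(out)
  }
  if (name == "all_branches") {
    grid <- expand.grid(y = 1:5, y0 = 1:5)
    rows <- lapply(seq_len(nrow(grid)), function(i) {
      fixture_row(k = 5L - grid$y[i], y0 = grid$y0[i], serious = FALSE,
                  prov = grid$y[i], muni = grid$y0[i], r = grid$y0[i])
    })
    return(do.call(rbind, rows))
  }
  # planted_opposite: deterministic background that cannot match the
  # opposite_assessments preset, plus 7 planted matches.
  n_bg <- 993L
  bg <- lapply(seq_len(n_bg), function(i) {
    serious <- i %% 7L == 0L          # some serious rows, but prov <= 3
    fixture_row(k = (i %% 5L), y0 = 1L + (i %% 3L), serious = serious,
                suspect = i %% 2L, r = 1L + ((i + 1L) %% 3L),
                muni = 1L + ((i + 2L) %% 3L), prov = 1L + (i %% 3L),
                new_ade = as.integer(i %% 11L == 0L), gender = i %% 2L)
  })
  planted <- lapply(1:7, function(i) {
    fixture_row(k = 1L, y0 = 1L, serious = TRUE, suspect = 1L, r = 1L,
                muni = 3L, prov = 4L, gender = i %% 2L)
  })
  out <- do.call(rbind, c(bg, planted))
  set.seed(77L)
  idx <- sample(seq_len(nrow(out)))   # fixed interleaving of planted rows
  out <- out[idx, , drop = FALSE]
  attr(out, "planted") <- which(idx > n_bg)
  out
}
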
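---
title: "Methods: automatic causality assessment and triage of ADR reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automatic causality assessment and triage of ADR reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Spontaneous reporting systems (SRS) collect adverse drug reaction (ADR)
reports in volumes far beyond what expert committees can review. Each
report carries a *causality assessment* on the WHO-UMC-style five-level
ordinal certainty scale (1 = unassessable/unclassifiable, 2 =
conditional/unclassified, 3 = possible, 4 = probable/likely, 5 =
certain), recorded at up to four tiers: the reporter, the reporter's
institute, and municipal- and provincial-level experts. Provincial
assessments — the most authoritative — exist only for a minority of
reports. `adrtriage` implements a pipeline that (i) learns a model of the
provincial assessment from eleven Boolean report items, (ii) scores every
report with a *warning signal* measuring how strongly the model disagrees
with the reporting side, weighted by event severity, and (iii) supports
brushing-style filtering and export for parallel-coordinates review.

## The ordinal assessment model

The core model is a cumulative logit (ordinal logistic) regression. With
$Y \in \{1,\dots,5\}$ the causality category and $x$ the 11 Boolean items
(five causality criteria and six severity criteria), the
proportional-odds form is

$$\operatorname{logit} P(Y \le j \mid x) = \theta_j + \beta^\top x,
\qquad j = 1,\dots,4 .$$

Two conventions deserve emphasis:

* **Sign.** We model $\theta_j + \beta^\top x$, so a *positive*
  coefficient pushes mass toward *low* (less certain) categories. Many
  packages use $\theta_j - \beta^\top x$; slopes must be negated when
  comparing (this is checked against `MASS::polr` in the test suite).
* **Cut points.** Only $J-1 = 4$ cut points are identifiable, because
  $P(Y \le 5) \equiv 1$.

The *parallel assumption* — one slope vector shared by all four
cumulative logits — is often violated in practice. The partial
proportional-odds (PPO) extension frees a subset $T \subseteq x$ of
variables:

$$\operatorname{logit} P(Y \le j \mid x) =
\theta_j + \beta^\top x_{\mathrm{par}} + \tau_j^\top x_{\mathrm{nonpar}} .$$

Non-parallel variables carry *only* the threshold-specific $\tau_j$
(no shared component); giving them both $\beta_k$ and $\tau_{jk}$ would
be redundant (a constant can be shifted between them), and dropping the
shared term resolves the identifiability cleanly. With an empty
non-parallel set the model reduces exactly to the proportional-odds
model, which the test suite asserts as a nesting identity.

Category probabilities are logistic-CDF differences,
$P(Y = j) = F(\eta_j) - F(\eta_{j-1})$ with $F(\eta_0) \equiv 0$ and
$F(\eta_J) \equiv 1$. Note that a denominator of the form
$1 - \exp(\cdot)$ sometimes seen in print is not a probability (it can
be negative or exceed one); the standard logistic inverse
$\exp(\cdot)/(1+\exp(\cdot))$ is what is implemented.

### Fitting, numerics and degenerate inputs

`fit_ppo()` maximizes the exact multinomial log-likelihood by BFGS with
analytic gradients, started from the closed-form intercept-only solution
(cut points at the empirical cumulative logits, zero slopes). That start
makes the intercept-only fit exact by construction and is already in the
right region for sparse Boolean designs. Convergence is declared when the
per-record gradient infinity norm falls below `grad_tol` (default 1e-6);
non-convergence yields a flagged result and a warning, never an
exception. Refitting with the same data and options is bit-identical.

Numerical policies, in order of appearance:

* **Probability floor.** During optimization category probabilities are
  floored at 1e-12 inside the log, which keeps the objective finite in
  crossing or separated configurations.
* **Crossing cumulative curves.** Cut points are fitted unconstrained.
  With threshold-specific $\tau_j$ the fitted cumulative curves can cross
  at some covariate pattern, implying a negative category probability.
  After fitting, monotonicity is checked at every training pattern and
  recorded in `monotone_ok`; at prediction time negative entries are
  floored at 1e-12 and the row renormalized, with the number of affected
  rows counted, attached as an attribute and warned about. Invalid
  probabilities are never returned silently.
* **Empty outcome categories.** A category absent from training leaves
  its cut point unidentified (it diverges). The default policy is an
  error naming the category; `empty_category = "merge"` instead collapses
  the scale to the categories present, records the mapping, and predicts
  zero probability for absent categories. In the real surveillance
  setting category 1 is essentially never assigned by provincial experts,
  so this policy is load-bearing, not hypothetical.
* **Separation.** A small optional ridge penalty on slopes
  (`ridge`, default 0) is available for quasi-complete separation;
  cut points are never penalized.
* **Prediction ties.** `predict_category()` takes the argmax and breaks
  exact ties toward the lower (less certain) category — the conservative
  direction for a triage tool.

### Choosing the non-parallel set

Which variables violate the parallel assumption is an empirical question.
`lr_test_parallel()` compares the all-parallel fit against the fit
freeing one variable: the alternative adds four threshold-specific
coefficients and removes one shared slope, so the likelihood-ratio
statistic is referred to $\chi^2_3$. `select_partition()` runs this test
for each predictor against the all-parallel null (not sequentially) and
frees the variables with $p < \alpha$, default $\alpha = 0.05$. This
per-variable screen is the simplest defensible procedure; its size is
verified by simulation in the acceptance suite (type-I error within
(0.03, 0.07) at $n = 1000$ over 500 replicates). Note the family-wise
consequence: under an all-parallel truth with $p$ tested variables the
selected set is empty with probability about $0.95^p$.

## The warning signal

Each report gets a score $\lambda = (s, t)$ comparing the model
assessment $Y$ with a recorded human assessment $Y^0$ (by default the
reporter-institute assessment, configurable to any of the four tiers).
The disagreement score is

$$d = \begin{cases}
|Y - Y^0| & (Y-3)(Y^0-3) > 0 \\
Y + Y^0 - 6 & (Y-3)(Y^0-3) = 0 \\
-|Y - Y^0| & (Y-3)(Y^0-3) < 0
\end{cases}$$

so $d$ is positive when both assessments fall on the same side of
"possible" and negative when they take opposite sides; the severity
weight is $r = 1$ for a normal and $r = 4$ for a serious ADE; and
$t = Y - Y^0$.

Two $s$ formulas ship because the published sources are internally
inconsistent: the literal rule $s = r\,(d+1)$ does not reproduce the
published worked examples (it gives $-8$ where $-12$ is printed, and
$-12$ where $-16$ is printed), whereas applying the $+1$ offset only for
$d \ge 0$ reproduces every printed value and the serious-report extreme
of $\pm 16$. The package defaults to that `table3_consistent` variant and
keeps `eq8_literal` selectable; shipping both documented variants was
preferred over guessing a single intent. `attainable_values()` enumerates
the exact value sets: for the default variant, normal reports span
$\{-4,\dots,-1\} \cup \{1,2,3\}$ and serious reports
$\{-16,-12,-8,-4\} \cup \{4,8,12\}$, so $|s| \ge 4$ identifies a serious
report (the single adjoining value is $s = -4$). Reports with a missing
$Y$ or $Y^0$ ($-1$) get an undefined signal and are excluded by filters.

## Baselines and evaluation

The comparison classifiers are multinomial logistic regression
(`nnet::multinom`, reference category 4 by default — the choice is a pure
reparameterization of the fitted probabilities, which the tests verify to
1e-6 — with tight optimizer tolerances) and a CART decision tree
(`rpart`, Gini impurity, `minbucket = 1`, `cp = 0`, no depth limit beyond
the implementation maximum). Both are reduced at fit time to plain
parameter states (coefficient matrix; node table) and predict from those
states, so JSON serialization round-trips cannot alter predictions.

All models are evaluated through one path: accuracy, per-class F1
(classes with zero predicted and zero true positives score 0), and
one-vs-rest ROC curves using the predicted class probability as score.
AUC is computed by a tie-grouped threshold sweep whose trapezoidal area
equals the Mann-Whitney concordance probability with ties counted one
half; the suite verifies it against an $O(n^2)$ pairwise oracle and
against `pROC`. The macro AUC is the unweighted mean over classes present
in the truth (absent classes are excluded, not counted as zero); the
micro AUC pools the $n \times 5$ indicator expansion.

## The synthetic generator

No real surveillance extract ships with the package; the generator
produces tables with the structure the pipeline assumes, and every
empirical claim in the tests is made on them.

* Predictors are *independent* Bernoulli draws. Default prevalences
  (causality items 0.70, 0.55, 0.45, 0.10, 0.20; severity items 0.02,
  0.01, 0.03, 0.04, 0.12, 0.08) were chosen once as plausible for
  spontaneous reports — common time-relationship and known-reaction
  flags, rare rechallenge, rare deaths, hospitalization the most common
  severe outcome (serious rate about 0.27 via the OR of the severity
  items).
* The true category is drawn from a PPO model with cut points
  $\operatorname{logit}(j/5)$ (uniform at zero covariates), ten parallel
  slopes frozen from a one-time standard-normal draw scaled by 0.8, and
  one non-parallel variable with $\tau = (-0.9, -0.3, 0.3, 0.9)$ — a
  spread of 1.8, clearly detectable yet monotone for every covariate
  pattern. A degenerate (crossing) true model aborts generation naming
  the offending pattern.
* The provincial assessment equals the true category, masked to $-1$ at
  rate 0.2 (partial expert review while keeping most labels available);
  reporter, institute and municipal assessments add independent clamped
  offsets with distribution (0.05, 0.15, 0.60, 0.15, 0.05) on
  $-2,\dots,2$ — a simple symmetric reporter-error model, declared
  rather than estimated, and configurable.
* Suspect-drug rate 0.8, new-ADE rate 0.1, gender rate 0.5.

What passing tests on these tables *do* show: the likelihood and its
maximizer are correct (oracle equivalence), estimators are consistent
(parameter recovery within 3 standard errors at $n = 5000$; bias
shrinking across $n = 400, 1600, 6400$), the parallel-assumption test
holds its size, and the signal/triage layers are exact. What they do
*not* show: performance on real reports, whose covariates are correlated,
whose categories are heavily unbalanced, and whose reporter errors are
not symmetric. Real-data headline numbers therefore cannot be — and are
not — reproduced here.

## Problem sizes used by the test and acceptance suites

Chosen as the package's own balance of statistical resolution against a
comfortably fast default run: likelihood-oracle checks on 20 datasets of
$n \le 50$; recovery at $n = 5000$; test-size calibration with 500
replicates at $n = 1000$; AUC oracle on 100 instances of $n \le 200$ plus
a 500-replicate permutation null; triage scan oracle on $10^4$ rows;
marginal-distribution check at $n = 5 \times 10^4$ against the exact
$2^{11}$-pattern sum. The whole suite runs in about a minute.

## Known limitations

* Covariate independence in the generator is a simplification; no attempt
  is made to mimic real marginal or joint distributions.
* The fitted model accepts real-valued predictors mathematically, but the
  schema and interfaces are Boolean-only.
* No Bayesian fitting, no links other than the logit, no confidence
  intervals on AUC, no calibration metrics.
* The interactive browser front end the triage layer feeds is out of
  scope: `export_viz()` writes the JSON contract plus a static SVG
  snapshot, and any parallel-coordinates front end can consume the JSON.
* Which variables are freed from the parallel assumption is decided by
  per-variable tests at a fixed level, without multiplicity correction;
  with many weakly informative predictors some false frees are expected.
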
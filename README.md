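# adrtriage

Automatic causality assessment and triage of spontaneous adverse drug
reaction (ADR) reports.

Spontaneous reporting systems collect far more ADR reports than expert
committees can review, and each report carries a causality assessment on
the WHO-UMC-style five-level certainty scale (1 =
unassessable/unclassifiable, 2 = conditional/unclassified, 3 = possible,
4 = probable/likely, 5 = certain), recorded by the reporter, the
reporter's institute, and municipal- and provincial-level experts.
`adrtriage` is for pharmacovigilance analysts and reviewers who want to

1. **model** the provincial expert assessment from eleven Boolean report
   items with a partial proportional-odds (PPO) cumulative logit
   regression,
2. **score** every report with a warning signal highlighting
   model-vs-reporter disagreement weighted by event severity, and
3. **triage** — filter reports with brushing-style conjunctive queries
   and export them for parallel-coordinates review.

A synthetic report generator with the same statistical structure makes
the whole pipeline testable without access to confidential surveillance
data.

## The model and the signal

The assessment model is the cumulative logit regression

```
logit P(Y <= j | x) = theta_j + beta' x_par + tau_j' x_nonpar ,   j = 1..4
```

over the 11 Boolean items of the report (five causality criteria, six
severity criteria). Parallel variables share one slope across the four
cumulative logits; non-parallel variables (selected by per-variable
likelihood-ratio tests, `select_partition()`) get threshold-specific
coefficients. **Sign convention:** positive coefficients push mass
toward *low* categories — many packages use `theta_j - eta`, so negate
slopes when comparing.

The warning signal per report is `lambda = (s, t)` with `t = Y - Y0` the
raw difference between the model assessment `Y` and a recorded human
assessment `Y0` (default: the reporter-institute assessment), and
`s` built from a signed disagreement score `d` (positive when both
assessments fall on the same side of "possible", negative on opposite
sides) scaled by a severity weight `r` (1 normal, 4 serious), so that
large negative `s` flags serious reports where model and reporter take
opposite sides. Two published-formula variants ship (the sources are
internally inconsistent); the default `table3_consistent` variant
reproduces all published worked examples. See the methods vignette
(`vignettes/adr-triage-methods.Rmd`) for the full account.

## Worked example

```r
library(adrtriage)

cfg     <- sim_config(n = 20000, seed = 42)       # synthetic study conditions
reports <- simulate_reports(cfg)
labeled <- reports[reports$prov_assess != -1, ]   # expert-reviewed subset

set.seed(42)                                      # 80/20 split
test_idx <- sample(nrow(labeled), round(0.2 * nrow(labeled)))
train <- labeled[-test_idx, ]; test <- labeled[test_idx, ]

part <- select_partition(train, alpha = 0.05)     # which items violate parallelism?
fit  <- fit_ppo(train, part)
fit
#> Partial proportional-odds causality-assessment model
#>   categories: 1,2,3,4,5   n_train: 12782   logLik: -17888.2
#>   parallel vars: 10   non-parallel vars: 1   converged: TRUE   monotone: TRUE
#>   cut points: -1.3399 -0.3688  0.4355  1.3950
#>   ...
#>   tau (per cut point):
#>      causality_assessment_5
#>   j1                -0.9295
#>   j2                -0.2304
#>   j3                 0.3466
#>   j4                 0.9206
```

The selection correctly frees the one variable the generator makes
non-parallel (`causality_assessment_5`, true tau −0.9 … 0.9), and the
cut points recover the true `logit(j/5)` values (−1.39, −0.41, 0.41,
1.39). Evaluation runs every model through the identical path:

```r
evaluate_model(fit, test)
#> Evaluation on 3196 reports
#>   accuracy : 0.3980
#>   F1 by class  : 1=0.5745  2=0.2468  3=0.1593  4=0.0101  5=0.2197
#>   AUC by class : 1=0.7107  2=0.5770  3=0.6364  4=0.6515  5=0.7018
#>   AUC macro: 0.6555   AUC micro: 0.7186
evaluate_model(fit_tree(train), test)
#>   accuracy : 0.3839 ...  AUC macro: 0.6385   AUC micro: 0.7029
```

(Accuracies are modest by design: the default generator draws weakly
informative Boolean items; what matters is that the ordinal model beats
the tree baseline through the same metrics.) Triage then extends and
filters the *full* table, including unreviewed reports:

```r
ext  <- extend_reports(reports, fit)      # adds auto_assess, risk_s, risk_t
hits <- filter_reports(ext, parse_predicates("suspect=1", "risk_s<-8"))
attr(hits, "n_matched")
#> [1] 594                                  # suspect drugs, strong disagreement

compute_signal(y = 4, y0 = 1, serious = TRUE)
#>   y y0 serious  d r   s t           variant
#> 1 4  1    TRUE -3 4 -12 3 table3_consistent
```

That last line is the canonical serious-report pattern: the model says
"probable/likely" (4), the institute said "unassessable" (1), so
`d = -3`, `r = 4`, `s = -12`, `t = 3` — a report worth a reviewer's
minute. `export_viz(ext, "viz.json", "viz.html")` writes the
parallel-coordinates export (axis order: New ADE, Serious ADE, Gender,
R/RI/Muni/Prov assess, Suspect, Auto assess, Risk s, Risk t; colors red
= category 1 through blue = category 5).

A command-line wrapper over the same functions ships at
`inst/cli/adrtriage.R` (subcommands `simulate`, `fit`, `signal`,
`filter`, `workflow`, `export-viz`); the column naming of report CSVs is
documented in `inst/extdata/report-schema.json`. The labels map to the
standard report items: `causality_assessment_1..5` are the five
causality criteria (time relationship, known reaction, dechallenge,
rechallenge, alternative explanation) and `severity_assessment_1..6` the
six seriousness criteria (death through other significant events).

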
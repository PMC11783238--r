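# bnscreen

Discrete Bayesian-network classifiers for early cancer detection from
routine clinical and laboratory data, with first-class support for
missing values.

## What problem this solves

Patients referred to a lung-cancer fast-track clinic arrive with
demographics (age, sex, smoking status) and a panel of ~20 routine blood
analyses — and, in practice, with holes in the data. `bnscreen` is for
biostatisticians and clinical-ML researchers who want to build and
stress-test detection models that handle those holes *natively*: a
discrete Bayesian network factorizes the joint distribution over the
outcome and predictors as

P(X₁,…,X_V) = ∏ᵥ P(Xᵥ | pa(Xᵥ)),

and the predicted risk is the exact posterior P(LC | observed predictors),
computed by variable elimination — a missing predictor is simply
marginalized, no imputation needed at prediction time.

The package implements the full experimental machinery around that model:

* **Discretization** of continuous labs: clinical reference intervals
  (sex-specific where appropriate, bundled registry) or supervised
  minimum-description-length (Fayyad–Irani) splitting learned per
  training fold.
* **Structure learning**: K2 greedy search scored by the
  Cooper–Herskovits marginal likelihood, with configurable ordering,
  parent cap (0–10) and an outcome-first start; plus an editable
  expert-elicited DAG fixture and an edge-agreement comparison.
* **Parameter learning**: Dirichlet-smoothed maximum likelihood on
  complete data, exact expectation-maximization under missingness
  (C++ core; exact joint family posteriors in the E-step).
* **Controlled degradation**: exact-count MCAR cell deletion at 0/10/20/30%
  (or any rate), reproducible from a seed, with a deletion log.
* **Evaluation**: stratified 10-fold cross-validation; Mann–Whitney AUC
  with Hanley–McNeil 95% CI; TPR/TNR at the 0.5 cutoff and TPR at fixed
  95% TNR; calibration bins (overall and stage-stratified); decision-curve
  analysis against flag-all / flag-none.
* **A ground-truth synthetic cohort generator** calibrated to published
  population marginals (25.2% prevalence, class-conditional smoking/sex/
  age rates, printed lab medians and IQRs), with labs coupled through a
  latent disease-severity factor so that the panel has the redundancy of
  real laboratory data — and an exact Bayes-oracle posterior for it.
* **The 16-model grid**: missingness level × DAG source × discretization,
  run end to end with per-model reports and tidy CSV/JSON artifacts.

## Worked example

Simulate a cohort, apply the 17-of-20 lab inclusion filter, and run a
reduced grid (two missingness levels, 5-fold CV to keep it quick):

```r
library(bnscreen)

cfg    <- generator_config(n = 2000, seed = 42)
cohort <- sample_cohort(config = cfg)
cohort <- apply_inclusion_filter(cohort)   # >= 17 of 20 labs observed
cohort
#> <bn_cohort> 1994 records, 502 LC (25.2%), 20 labs

grid <- experiment_grid(levels = c(0, 0.3), cv_folds = 5, seed = 42)
res  <- run_grid(grid, cohort)
res$summary[, c("model_id", "level", "dag_source", "discretization",
                "auc", "tpr_at_tnr95")]
#>   model_id level dag_source discretization   auc tpr_at_tnr95
#> 1        1   0.0    learned       clinical 0.732        0.173
#> 2        2   0.0    learned            mdl 0.728        0.181
#> 3        3   0.0     expert       clinical 0.729        0.171
#> 4        4   0.0     expert            mdl 0.733        0.179
#> 5        5   0.3    learned       clinical 0.707        0.173
#> 6        6   0.3    learned            mdl 0.686        0.159
#> 7        7   0.3     expert       clinical 0.699        0.147
#> 8        8   0.3     expert            mdl 0.689        0.165
```

Each row is one model of the grid. `auc` is the pooled out-of-fold area
under the ROC curve: at this small n, deleting 30% of the observed
predictor cells costs only a few hundredths of AUC, because inference
marginalizes the missing cells and the correlated lab panel makes them
partially redundant. `tpr_at_tnr95` is the sensitivity when specificity
is pinned at 95% — the operating point most relevant for screening
referral. A single model's full report:

```r
res$reports[[2]]
#> <model_report> model 2 | missing 0% | learned DAG | mdl discretization
#>   AUC 0.728 (0.701-0.755), TPR@0.5 0.305, TNR@0.5 0.902, TPR@TNR95 0.181
```

The report also carries calibration bins (predicted risk vs observed
event rate in 0.1-wide bins), a stage-stratified histogram, the decision
curve (net benefit vs threshold), the pooled scores, and the learned DAG
of every fold; `write_report()` emits JSON plus tidy CSVs for the curves.

Lower-level entry points compose the same pipeline by hand:
`discretize_cohort()` + `inject_mcar()` + `k2_search()` / `load_expert_dag()`
+ `em_fit()` + `predict_risk()` / `query_posterior()`.

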
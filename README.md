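# hftraj — dynamic 30-day readmission risk trajectories for heart failure

Patients hospitalized with heart failure have the highest 30-day
readmission rates of any major diagnosis group, and the standard risk
models score them only once — at admission, when little is known, or at
discharge, when it is too late to act. `hftraj` implements a dynamic
alternative: the 30-day readmission risk is re-estimated on every day of
the hospital stay, *as if the patient were discharged that day*, and the
resulting per-patient risk trajectories are clustered into qualitatively
different in-hospital courses (decreasing, high, moderate, low risk) whose
distinguishing clinical predictors are then identified.

Daily outcomes are counterfactual (nobody observes the readmission outcome
of an earlier discharge that did not happen), so the package uses a
two-stage proxy-outcome design:

1. **Stage 1.** Logistic regression of observed 30-day readmission on
   everything known at discharge —
   `logit P(readmit) = β₀ + xᵀβ` — with backward elimination and
   stratified 5-fold cross-validation; `x` contains nine engineered
   time-series characteristics per vital/lab (count, mean, SD, extremes,
   normalized extremum indices, recent mean, mean first difference), plus
   first-minus-last changes, event counts, statics and the Charlson index.
2. **Counterfactual daily risks.** The held-out stage-1 fold models are
   applied to features truncated at each milestone (admission, 6 AM of
   days 1–5, discharge).
3. **Stage 2.** A beta regression (logit mean link, constant precision φ)
   re-predicts these proxies from the truncated features — the deployable
   daily model, summarized by pseudo-R² (squared Pearson correlation) and
   a Kolmogorov–Smirnov check of the beta assumption.
4. **Trajectories.** Seven-milestone risk vectors per encounter are
   clustered by seeded K-means (k-means++, 50 restarts) and labelled;
   Kruskal–Wallis tests screen the predictors separating the groups.

No hospital data ship with the package: a synthetic-EHR generator with
planted risk-trajectory archetypes (a first-class, tested module) emulates
the cohort schema — irregular measurement times, per-lab missingness, ~20%
readmission prevalence, 1–14-day stays — and provides ground truth for
every downstream stage. See the vignette
(`vignettes/dynamic-readmission-trajectories.Rmd`) for the model details
and design choices.

## Worked example

The analysis is organized as numbered drivers under `analysis/`:

```sh
Rscript analysis/01_generate_cohort.R     # synthesize the 534-encounter cohort
Rscript analysis/02_build_features.R      # engineered predictor matrix
Rscript analysis/03_run_pipeline.R        # both model stages + clustering
Rscript analysis/04_trajectory_recovery.R # planted-archetype recovery
```

Step 1 prints the cohort it wrote:

```
cohort: 534 encounters, 2649 patient days
readmitted: 105/534 (19.7%)
decreasing       high        low   moderate
       125        110        104        195
```

i.e. a cohort at the configured ~20% prevalence with the four planted
trajectory archetypes at their configured mix. Step 3 runs the full
two-stage analysis and reports:

```
== encounter-level model ==
selected predictors: 27
out-of-sample AUC: 0.678 (SD 0.066)

== daily model ==
pseudo R-squared: 0.437 in-sample, 0.352 cross-validated
KS vs fitted Beta(0.24, 0.77): D = 0.086, p = 0.001

== trajectory groups ==
moderate   141/534 (26.4%)
low        179/534 (33.5%)
decreasing 134/534 (25.1%)
high       80/534 (15.0%)
```

The AUC is the cross-validated discrimination of the encounter-level
model (an AUC near 0.7 is the realistic range for readmission models);
the pseudo-R² measures how well the daily beta regression reproduces the
held-out counterfactual proxies; and the trajectory groups include a
*decreasing* cluster — a quarter of encounters whose estimated risk falls
steeply from admission to discharge (centroid 0.68 → 0.26 in this run) —
alongside flat high/moderate/low courses. Step 4 verifies the clustering
machinery against the generator's ground truth (adjusted Rand index 0.973
at n = 1000) and shows recovery degrading gracefully as the planted
separation is scaled toward zero. All artifacts (cohort CSVs, feature
matrix with its imputation sidecar, fitted-model JSONs, daily risk table,
cluster assignments and centroids, Kruskal–Wallis table, temporal
profiles, and a JSON + Markdown report) land under `results/`.

Everything is driven by exported package functions
(`generate_cohort()`, `build_feature_table()`, `assemble_matrix()`,
`cross_validate()`, `backward_eliminate()`, `fit_beta_regression()`,
`kmeans_cluster()`, `screen_discriminants()`, …), with
`run_pipeline(pipeline_config(...))` as the one-call orchestrator.

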
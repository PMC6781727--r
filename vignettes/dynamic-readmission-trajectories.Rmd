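---
title: "Dynamic 30-day readmission risk trajectories for heart failure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic 30-day readmission risk trajectories for heart failure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hftraj)
```

## The problem

Patients hospitalized with heart failure have very high rates of all-cause
readmission within 30 days of discharge. Most readmission models are static:
they score a patient once, either at admission (when little clinical data
exist) or at discharge (too late to act). `hftraj` implements a *dynamic*
alternative: a 30-day readmission risk is re-estimated every day of the
stay, as if the patient were discharged that day, and the resulting
per-patient risk *trajectories* are clustered to reveal qualitatively
different in-hospital courses — a group whose risk falls steadily as
treatment takes effect, and groups whose risk stays high, moderate or low
throughout.

The fundamental obstacle is that daily outcomes are counterfactual: we never
observe whether a patient discharged on day 3 *would have been* readmitted,
because they were not discharged on day 3. The package follows a two-stage
proxy-outcome strategy:

1. **Stage 1 (encounter level).** A logistic regression of the observed
   30-day readmission outcome on everything known at discharge, with
   backward elimination. Writing $x_i$ for the discharge-time feature vector
   of encounter $i$,
   $\Pr(Y_i = 1 \mid x_i) = \operatorname{logit}^{-1}(\beta_0 + x_i^\top \beta)$.
2. **Counterfactual daily risks.** The stage-1 model is applied to the same
   encounter's features *truncated* at each in-stay milestone $t$ —
   admission, 6 AM of days 1–5, discharge — giving the estimated risk had
   the patient left at $t$.
3. **Stage 2 (daily level).** These stage-1 proxies, which live in $(0,1)$
   and are checked against a beta law (maximum-likelihood shape fit plus a
   Kolmogorov–Smirnov test), become the outcome of a beta regression with a
   logit mean link and constant log-parameterized precision $\phi$:
   $y_{it} \sim \mathrm{Beta}(\mu_{it}\phi, (1-\mu_{it})\phi)$,
   $\operatorname{logit}(\mu_{it}) = z_{it}^\top \gamma$, where $z_{it}$
   are the milestone-truncated features. This is the deployable daily
   model. Its performance is summarized by a pseudo-$R^2$: the squared
   Pearson correlation between proxies and predictions.
4. **Trajectories.** Each encounter's seven milestone predictions (short
   stays carry the discharge value forward into unreached milestones) are
   clustered by K-means (Lloyd's algorithm, k-means++ initialization, best
   of many restarts), and the $k = 4$ clusters are labelled decreasing /
   high / moderate / low by an explicit rule. Kruskal–Wallis tests then
   screen which predictors separate the groups, and group-by-milestone
   means profile how those discriminants evolve in time.

Because no hospital data ship with the package, a synthetic-EHR generator
is a first-class module: it emulates the schema and the statistical
structure the analysis assumes, with planted trajectory archetypes serving
as ground truth for every downstream stage.

## Engineered features

For every vital sign and laboratory variable, nine time-series
characteristics are computed over exactly the measurements observed up to
the prediction time: the count $n$, mean, SD (0 when $n=1$), minimum,
maximum, the *normalized index* of the minimum and of the maximum (1-based
position of the extremum divided by $n$; ties resolved by first occurrence,
so an all-equal series of length 5 has index 0.2), the mean of the last
three values, and the mean first-order difference (0 when $n=1$). A tenth
derived feature is the first-minus-last change. The normalized index
captures *when* in the observed window the extreme occurred: if the
minimum of 10 temperature readings is the 6th, the index is
$6/10 = 0.6$; a patient whose minimal potassium falls on day 3 of a 6-day
stay (one draw per day) has index $0.5$ on the full stay but $1.0$ when the
series is truncated at day 3 — the same fact, structured differently for
the encounter-level and daily models.

Statics (demographics, insurance, marital status, discharge disposition,
chief complaint, ZIP group) are dummy-encoded against fixed level sets; the
Charlson comorbidity index is computed from ICD-9 codes with the Deyo
administrative mapping and original weights (severe members of the
diabetes/liver/malignancy hierarchies supersede mild ones). Counts of
medication orders and procedures per category complete the row, plus the
elapsed length of stay in days.

Laboratory variables entirely unmeasured for more than 30% of encounters
are dropped as whole feature families; remaining missing values are imputed
with the training-cohort column mean (an encounter with no measurements has
no within-encounter mean to use), and the binary missing indicator is kept
as a predictor in its own right. Imputation means are learned on training
folds only and re-applied unchanged to held-out data.

## Prediction clock

Predictions are made at admission, at 6 AM of each subsequent day, and at
discharge. Day $k$'s cutoff is the first 6 AM strictly after admission plus
$(k-1)\cdot 24$ h, kept while it falls inside the stay. The admission
prediction uses a 2 h window: the generator places the admission workup
(one measurement of every available variable) inside the first two hours,
so the admission milestone sees the presenting state rather than an empty
record.

## Model-fitting choices

* **Logistic MLE.** `stats::glm` (IRLS) on internally standardized
  features, coefficients reported on the original scale; aliased columns
  dropped with a warning. If the fit separates (non-convergence or fitted
  probabilities pinned at 0/1) the model is refit by damped Newton with an
  L2 penalty of 1 per standardized coefficient — the equivalent of a
  standard-normal prior, chosen because the candidate pool (~200 columns
  for ~85 events) makes weaker penalties degenerate: coefficients blow up
  along separating directions and every Wald test looks significant, which
  stalls elimination.
* **Backward elimination** removes the term with the largest p-value while
  it exceeds `alpha_remove = 0.05` (the common convention; the threshold is
  an argument). Multi-column dummy blocks are tested jointly with a Wald
  chi-square on the block coefficients rather than a likelihood-ratio
  refit: the two are asymptotically equivalent, and the refit variant costs
  one extra IRLS fit per block per step, which at ~170 starting terms is
  thousands of fits per fold for no inferential gain.
* **Cross-validation** is stratified by outcome with 5 folds. Encounters
  are treated as independent even when one patient contributes several —
  deliberately, matching how the tool would score encounters in real
  time — with grouped-by-patient folds available via the `group` argument;
  *everything* — imputation means, the missingness filter, elimination — is
  re-learned inside each training fold, and the AUC (computed by the
  midrank Mann–Whitney identity, ties counted one half) is evaluated on the
  held-out fold only.
* **Counterfactual targets are taken out-of-fold**: each encounter's daily
  proxies come from the stage-1 model of the fold that held it out. This
  matters. If stage 2 is fed proxies produced by the very model whose
  feature set it shares, the proxy is an exact logit-linear function of the
  regressors and the beta regression reproduces it perfectly
  (pseudo-$R^2 \equiv 1$, $\phi \to \infty$) — the second stage would be an
  identity in disguise. With out-of-fold proxies the targets mix five
  slightly different fold models, no single map can reproduce them, and
  the pseudo-$R^2$ becomes an honest measure.
* **Beta regression** maximizes the exact beta log-likelihood by BFGS with
  analytic gradients from a least-squares warm start on logit targets;
  targets are first compressed away from the boundary by
  $y' = (y(n-1) + 0.5)/n$, so the pipeline can never hand the likelihood an
  exact 0 or 1. Precision is constant by default (one $\phi$), with a
  per-group option (`phi_groups`, e.g. one $\phi$ per milestone); standard
  errors come from the numerical Hessian.
* **K-means** is Lloyd's algorithm with k-means++ seeding, 50 restarts by
  default, empty clusters re-seeded from the farthest point, and full
  determinism under a seed. The pipeline fixes $k=4$ because four
  qualitative courses are the object of study, and emits an inertia-by-$k$
  profile in the report so the choice is inspectable. The labelling rule is an explicit convention:
  with $k=4$, the centroid with the largest admission-to-discharge drop is
  "decreasing" provided the drop exceeds 0.15; the others are
  high/moderate/low by mean level; if nothing drops enough, all four are
  labelled by level with a logged notice.
* **Kruskal–Wallis screening** uses the tie-corrected rank statistic
  (`stats::kruskal.test`) per numeric feature at its discharge-time values,
  at a raw $p < 0.001$ threshold with *no* multiplicity correction — the
  screen is deliberately a raw-p convention; pass the returned table
  through `stats::p.adjust` for a corrected variant. A fully tied feature
  is reported as $H=0$, $p=1$.

## What the generator emulates — and what it does not

`generator_config()` defaults *are* the study conditions: 534 encounters
(when run via the bundled analysis scripts), a 20% readmission base rate,
archetype mix 24.5 / 21.2 / 33.1 / 21.2 % (decreasing / high / moderate /
low), stays of 1–14 days with a log-normal length distribution tuned to a
4-day median and ~4-day IQR, per-lab total-missingness rates led by proBNP
(13.1%), AST (10.3%) and troponin (6.9%), and measurement streams (a
guaranteed admission workup plus a Poisson process per variable per day)
over a 16-variable vital/lab panel.

Each encounter draws a latent risk-score curve from its archetype:
piecewise-linear between the milestone anchors, decreasing from 0.69 to
0.30, high flat at 0.75, moderate flat at 0.61, low 0.39 to 0.21, plus a
Gaussian per-encounter level shift (SD 0.03) and small per-milestone jitter
(SD 0.015). The dynamics unfold over a canonical 120 h window — risk
movement concentrates in the first five days, as does most clinical
activity (labs, procedures, medication orders) in heart-failure stays — so
a short stay realizes only part of a decreasing curve. Measurement
values follow the *current* score through per-variable effect sizes (lower
hemoglobin, sodium, diastolic pressure and SpO2 at higher risk; higher BUN,
creatinine, proBNP, troponin, pulse and respiratory rate; potassium tracks
the in-stay score *change*, emulating diuretic-driven potassium loss during
decongestion). Statics reflect the state at presentation (past-visit counts
and comorbidity burden follow the admission score), and event intensities
follow the current score day by day — deliberately, so that admission-time
data cannot reveal who will recover; that distinction has to emerge from
the evolving measurements, which is precisely what the dynamic model is
for.

Two calibrations tie the score scale to outcomes. First, the
score-to-probability link has a logit-scale slope (`outcome_scale`, default
1.6) that widens the spread of true discharge risks; it is chosen so the
cohort's *ideal* discriminability (AUC of the true risk against the
realized outcome) sits near 0.8, which puts a realistically fitted model in
the low-0.7s — the range dynamic readmission models actually attain.
Second, a logit-scale offset is solved at generation time so the realized
mean discharge probability equals the configured base rate exactly; the
reported cluster-level risks (0.3–0.75) could not otherwise coexist with a
20% prevalence. Readmission is then a Bernoulli draw at the discharge-day
risk, and the truth table records the archetype and the calibrated risk at
all seven milestones — in a separate file, so pipeline code cannot consume
it by accident.

Not emulated: inter-variable correlation beyond the shared latent score
(vitals and labs are conditionally independent given the score),
pharmacokinetics, ICD-9 realism beyond a small Charlson-testable
vocabulary, transfers between hospitals, and any real-data idiosyncrasies
of measurement scheduling. Passing tests on this cohort therefore
demonstrate that the *pipeline machinery* recovers planted structure under
the stated conditions — not that the same numbers would arise from any
particular hospital's records.

## Known limitations and degenerate behavior

* Counterfactual risks at early milestones are extrapolations: stage 1 is
  trained on discharge rows, so at an admission cutoff the count features
  sit far outside their training range and the early counterfactuals are
  inflated relative to any calibrated admission risk. This is inherent to
  the design — an early counterfactual effectively answers "what if the
  current state were the discharge state", which overstates risk in a
  cohort that improves in hospital — and is why the package's recovery
  checks compare model output with planted truth at the discharge
  milestone, where the model is in-domain.
* The 7-point trajectory comparison is blunt for short stays: a 1–2-day
  decreasing-archetype encounter is padded with its discharge value and can
  legitimately resemble a low-risk encounter. Cluster membership near that
  boundary is genuinely ambiguous.
* With ~85 events per training fold against a ~200-column pool, backward
  elimination is statistically noisy however it is computed; selected sets
  vary across folds, and the cross-validated AUC — not the selected feature
  list — is the stable summary.
* Problem sizes in the tests (a 534-encounter pipeline run, 300-encounter
  module fixtures, 1000-encounter recovery checks, 4000–5000-row parameter
  recovery) were chosen as the smallest sizes at which the statistical
  assertions are stable across seeds.
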
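---
title: "Developing center-adjusted biomarker combinations with akibma"
author: "akibma authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Developing center-adjusted biomarker combinations with akibma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(akibma)
```

## The problem

Acute kidney injury (AKI) is a common complication of cardiac surgery, and
a patient's risk is best assessed immediately after surgery — days before a
serum-creatinine-based diagnosis is possible. A panel of kidney-injury,
cardiac and inflammatory biomarkers measured 0–6 h after surgery, together
with cardiopulmonary bypass (CPB) time, offers candidate predictors; the
task is to find a small *combination* with strong prognostic capacity.

Two features of multicenter biomarker studies make this harder than a
textbook variable-selection exercise:

* **Center effects.** Assay batches, populations and practice differ by
  center, so both biomarker distributions and outcome rates vary across
  centers. A combination that merely encodes "which center is this patient
  from" can look discriminating while carrying no within-center
  information. Every model here therefore forces center indicators into
  the fit, and performance is measured by a *center-adjusted* AUC.
* **Selection bias.** Searching millions of candidate models and then
  evaluating the winner on the same data overstates performance. The
  package implements bootstrap optimism correction in which the *entire*
  selection procedure — not just the coefficient fit — is repeated in
  every resample.

`akibma` packages this workflow end to end: a candidate-predictor schema
and cohort I/O, Bayesian model averaging (BMA) for center-adjusted
logistic regression, adjusted-AUC estimation, internal validation,
split-sample comparison against frequentist selection, prognostic
enrichment for trial design, a mortality-association analysis, and a
synthetic multicenter cohort generator that makes all of it testable
without patient data.

## Bayesian model averaging for logistic regression

With $p$ candidate predictors $X_1,\dots,X_p$ (here $p = 23$: 22
biomarkers plus CPB time) and forced center indicators, each model $M_k$
is a subset of the candidates fit by center-adjusted logistic regression:

$$
\mathrm{logit}\, P(Y = 1 \mid X, C) \;=\; \alpha^{(C)} +
\sum_{j \in M_k} \beta_j X_j ,
$$

where $\alpha^{(C)}$ are center-specific intercepts (reference-cell
encoding, $C-1$ indicator columns). Skewed biomarkers enter on the
natural-log scale; the signed change in serum creatinine and CPB time
enter linearly (`aki_predictors()` records the transform per candidate).

Each candidate receives a prior inclusion probability $\pi$ (default
$1/2$), inducing the model prior
$P(M_k) \propto \pi^{|M_k|}(1-\pi)^{p-|M_k|}$ — with $\pi = 1/2$, every
one of the $2^{23} = 8{,}388{,}608$ models has prior probability
$(1/2)^{23} \approx 1.19\times 10^{-7}$. The integrated likelihood of each
model is approximated through its BIC, the standard device for BMA in
generalized linear models:

$$
P(M_k \mid \text{data}) \;\propto\;
\exp\!\left(-\tfrac{1}{2}\,\mathrm{BIC}_k\right) P(M_k),
\qquad
\mathrm{BIC}_k = -2\,\hat\ell_k + d_k \log n ,
$$

with $d_k$ counting the intercept, the forced center indicators and the
included candidates. Models whose posterior odds against the best model
exceed the Occam's-window ratio (default 20) are discarded and the
survivors renormalized. The posterior variable probability of candidate
$j$ is the summed posterior of retained models containing it. Two
combinations are then read off the posterior:

* the **maximum posterior model probability combination** (ties broken
  toward the smaller model, then the lexicographically smaller subset);
* the **median probability combination** — all candidates whose posterior
  variable probability strictly exceeds 0.5.

### Searching the model space

For $p \le 16$ the package enumerates all subsets and fits each by exact
IRLS. For larger panels it follows the classical two-stage strategy: the
full model is fit by IRLS, the weighted least-squares problem defined by
the final working response and weights is formed, and a branch-and-bound
best-subsets search (implemented in compiled code) returns the `nbest`
(default 50) lowest-RSS subsets per model size. The branch-and-bound is
exact for the linearized problem: excluding a variable can only raise the
RSS, so a subtree whose relaxation already exceeds the current nbest-th
best RSS at every attainable size is pruned. Exact logistic BICs are then
recomputed for every screened-in candidate, so the linearization only
affects which models are *screened*, never the probabilities of retained
models. On synthetic cohorts the two routes select identical combinations
in essentially every dataset and identical posteriors whenever their
retained model sets coincide; the test suite checks this against full
enumeration at $p = 10$.

### Numerical choices

* IRLS declares convergence when the largest coefficient change falls
  below $10^{-8}$ within 25 iterations, with step-halving so the
  log-likelihood never decreases.
* Quasi-separation is a fact of life in these cohorts: markers with
  detection floors are near-constant, small centers can be conditionally
  separated, and then some coefficient drifts while the likelihood is
  flat. Such fits are flagged (`converged = FALSE`, `separated = TRUE` on
  direct use of `fit_logistic()`), but for posterior computation a fit
  whose log-likelihood has stabilized (relative change below $10^{-8}$)
  is retained: its maximized likelihood, and hence its BIC, is
  well-defined, which matches how deviance-converged GLM fits behave in
  standard BMA software. Rank-deficient fits are always dropped, with a
  warning.
* The prior $\pi$, the Occam ratio, `nbest` and the search mode are all
  exposed in `bma_config()`; at $\pi = 1/2$ the model-prior term cancels
  and posteriors depend on BIC differences alone.

## Center-adjusted AUC

A combination is scored as the biomarker linear predictor only,
$M = \sum_j \hat\beta_j X_j$: intercept and center terms are excluded, so
the score is a pure biomarker combination (they would not change
within-center ranks in any case). Discrimination is summarized by the
covariate-adjusted AUC: the Mann–Whitney AUC is computed within each
center and averaged with weights proportional to the number of cases per
center (pair-count weighting is available via `weighting = "pairs"`; the
case weighting is the default because it matches the case-mix
standardization of the covariate-adjusted ROC methodology). Centers
lacking a case or a control in a given dataset — routine in bootstrap
resamples — contribute no within-center information and are dropped with
a record. The adjusted AUC is invariant to any within-center monotone
transformation of scores, and under a center-confounded null (scores and
outcome rates both shifted by center, no within-center signal) it stays
near 0.5 where the pooled AUC is inflated — the motivating property,
exercised directly in the test suite.

## Internal validation

Apparent (resubstitution) performance is estimated by running the
selector on the full data, refitting the selected combination, and
evaluating its adjusted AUC on the same data. The optimism of this
estimate is measured by a bootstrap (default 1000 replicates; 200 are
used in the package's own experiments to keep them desk-scale): each
replicate resamples subjects with replacement, reruns the *entire*
selection (including the model-space search), refits, and compares the
replicate-fit combination's AUC on the resample with its AUC on the
original data. The mean difference is subtracted from the apparent AUC,
and the 95% CI is the percentile interval of the replicate (resample)
AUCs shifted by the same mean optimism and clipped to $[0,1]$.

Decisions the package fixes (and exposes in `validation_config()`):

* Resampling is stratified by center by default, so every center is
  present in every replicate and center-adjusted fitting is always
  defined; a plain bootstrap is available.
* A replicate (or the full data) may select the *empty* combination; an
  empty combination has no discrimination and scores 0.5. Dropping such
  replicates would bias the optimism estimate downward.
* The secondary outcome (severe AKI) is evaluated inside the same
  bootstrap loop, reusing each replicate's primary-outcome selection and
  coefficients, so the cross-outcome corrected AUC reflects one selection
  flow, not a second selection.

One behavior worth knowing: when selection is very unstable — for
instance under a global null, where the full-data selection is almost
always empty (BIC is consistent, so the null model wins) but occasional
resamples pick up a spurious predictor — the apparent AUC sits at 0.5
while the mean optimism is slightly positive, so the corrected AUC lands
slightly *below* 0.5. The correction is conservative in this corner; the
acceptance experiments quantify it.

## Comparing selection strategies

The exploratory harness repeatedly halves the data (cases split as evenly
as possible, controls likewise, the training half taking any odd
remainder), runs four selectors on the training half — BMA
maximum-posterior, BMA median-probability, forward selection (Wald entry
p < 0.1), and univariate selection (all candidates with single-predictor
Wald p < 0.1, refit jointly) — and evaluates each selected combination,
refit on the training half, by adjusted AUC on the held-out half only.
Wald tests were chosen over likelihood-ratio tests because they need a
single fit per candidate step; the univariate-selected set is refit
jointly because a combination needs one score. On default synthetic
cohorts the four methods land within a few hundredths of AUC of each
other while the BMA combinations stay markedly smaller than forward and
especially univariate selections — the parsimony pattern the method is
valued for.

## Prognostic enrichment and mortality

For trial design, `enrichment_table()` tabulates, per score threshold
$q \in \{0, .25, .5, .75\}$: the number screened per eligible patient
($1/(1-q)$ exactly; 1.3, 2 and 4 at the three nonzero thresholds), the
event rate among screen positives (subjects strictly above the empirical
$q$-quantile, quantile type 7 on the full analysis cohort), and the total
two-arm trial size at that event rate. Sample sizes use the unpooled
two-proportion normal approximation (per-arm ceiling, two equal arms);
published tables of this kind rarely state their exact routine and
variants differ by under a percent, so the package treats a Monte-Carlo
power simulation (`simulate_trial_power()`, pooled two-proportion z-test)
as the ground truth and verifies the returned sizes deliver 88–92% power
at a 90% target across control-arm rates.

The mortality analysis takes a *fixed* combination (coefficients from the
AKI model, not re-estimated), standardizes the score to unit sample SD on
the mortality complete-case set, and fits a center-adjusted logistic
regression for death at a fixed horizon, reporting the odds ratio per SD
with a Wald CI. Complete cases are defined by the combination's own
biomarkers, not the full candidate panel.

## The synthetic cohort generator

No patient-level data ship with the package; `generate_cohort()` stands
in for a multicenter postoperative cohort so that every stage is
exercisable and testable. Its defaults describe the study conditions the
pipeline is meant for:

* 1219 subjects across six centers with uneven shares
  (9/5/9/44/4/29%); sustained mild AKI prevalence 117/1219 and severe
  AKI 60/1219, with 55 of 60 severe cases also mild.
* Right-skewed biomarkers: correlated Gaussian on the log scale
  (exchangeable $\rho = 0.3$ — real marker covariance is not public, and
  an exchangeable stand-in induces realistic selection competition),
  exponentiated, with per-marker location/scale set from typical
  postoperative concentration medians and IQRs.
* Assay detection floors for plasma EGF (0.90 pg/mL) and VEGF
  (4.5 pg/mL), applied as exact lower bounds so the floor value recurs
  with positive frequency; CPB time normal (mean 114.2, SD 59.9 min)
  bounded below at zero; a signed change-in-creatinine variable.
* Center structure on *both* sides: every marker is shifted per center by
  a $N(0, 0.3)$ multiple of its SD, and centers carry outcome-intercept
  offsets (−0.53 to +0.47 log-odds), so center adjustment is genuinely
  needed rather than decorative.
* A sparse true signal: log NT-proBNP, log h-FABP and the creatinine
  change carry coefficients 0.6, 1.15 and 6.0 on the transformed scale —
  odds ratios of roughly 1.8 and 3.2 per log unit and 1.8 per
  0.1 mg/dL, the magnitudes typical of the strongest postoperative
  markers. They are sized by a design calculation: each effect per
  predictor SD, divided by its coefficient standard error at this cohort
  size and prevalence (including the variance inflation from the
  exchangeable predictor correlation), must clear the BIC inclusion
  threshold `sqrt(log n)` with about a two-SD margin, so the median
  probability model recovers the triple in the large majority of
  generated cohorts. The mild-AKI intercept is
  calibrated per generated cohort (monotone root-finding) so the expected
  prevalence hits its target exactly.
* Severe AKI nests within mild AKI: conditional on mild status, severe
  risk rises with the same latent predictor (slope 0.5), with the
  conditional intercept calibrated to the 55/117 overlap target and a
  small independent rate (5/1102) among non-mild subjects — so the
  severe/mild overlap is high but not total.
* Death at 1 and 3 years follows a logistic model in the standardized
  latent predictor (slope $\log 1.6$ per SD), calibrated to 1-year and
  3-year mortality targets of 4.4% and 9.5%.
* Missingness is MCAR per predictor cell, at a rate chosen so that the
  complete-case fraction is about 899/1219 (the reported similarity of
  outcome prevalence between complete and incomplete subjects is what an
  MCAR mechanism produces, and nothing in the pipeline models the
  missingness mechanism itself).

What the generator deliberately does **not** emulate: the true
between-marker covariance (only exchangeable), assay harmonization and
unit conversions, informative missingness, censoring of vital status, or
the exact marginal medians/IQRs of any particular study. Tests passing on
these cohorts therefore certify the *procedure* — selection, adjustment,
optimism correction, enrichment arithmetic — not any cohort-specific
estimate.

## Problem sizes used by the experiments

The package's own experiments (test suite and `scripts/acceptance.R`) run
at sizes chosen to be informative yet desk-scale, and state them
explicitly: search-equivalence on 50 cohorts of $n = 900$ at $p = 10$;
null-data optimism correction over 20 cohorts with 200 bootstrap
replicates each; recovery of the planted combination over 50 full-scale
cohorts; selector comparison over 30 half-splits; Monte-Carlo power with
10,000 simulated trials per event rate. The procedure defaults
(`n_boot = 1000`, `n_splits = 1000`) remain the recommended settings for
a real analysis.

## Known limitations

* Posterior probabilities rest on the BIC approximation; no exact Bayes
  factors or MCMC over model space.
* The combinations are prognostic scores, not risk prediction models:
  forcing center into every fit means there is no portable intercept, so
  calibration is out of scope by construction.
* Complete-case analysis only; no imputation machinery.
* The optimism-corrected AUC can be slightly conservative when selection
  is unstable (see above).
* Mortality is analyzed at fixed horizons by logistic regression; no
  time-to-event modelling.
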
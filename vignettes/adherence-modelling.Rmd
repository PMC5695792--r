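---
title: "Modelling medication adherence from claims: methods and design notes"
author: "ehrAdherence"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Modelling medication adherence from claims}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

About half of patients prescribed a statin stop refilling it within a year.
Predicting, at the time of the first fill, who will not adhere would let a
health system target its (expensive) adherence interventions. Administrative
claims — pharmacy fills, laboratory results, diagnostic and procedure codes —
are the data a health system already has, but they are sparse, redundant and
month-truncated. This package implements a complete modelling pipeline for
that setting, organised around a patient's *threshold date*: the month of
the first statin fill. Everything observed before the threshold is a
potential predictor; everything after it is outcome.

The pipeline has seven stages, each an exported function (`runPipeline()`
chains them):

1. **Cohort** (`applyCohortFilters()`): treatment-naive adults (18–65) with
   a flagged first statin fill of a standard duration (30/60/90/180 days)
   and at least a year of follow-up.
2. **Features** (`buildCountMatrix()`, `extractBaselineLabs()`,
   `computePriorPdc()`, `interactionCounts()`): pre-threshold claim-count
   matrix, most-recent lab values, prior adherence to other medications,
   and per-kind utilisation counts.
3. **Factorization** (`fitNmf()`): nonnegative matrix factorization of the
   count matrix into K factors (default 30) with per-patient factor scores.
4. **Outcomes** (`computePdc()`, `lipidChange()`, `eventOutcomes()`):
   percent days covered (PDC) and the adherence label PDC > 80%,
   cholesterol change around initiation, and time-to-hospitalization per
   diagnosis group.
5. **Disease risk** (`fitDiseaseRisk()`): multi-outcome penalized logistic
   model of 1-year hospitalization, cross-validated, whose composite
   probability becomes a covariate downstream.
6. **Adherence** (`fitAdherence()`, `variableImportance()`,
   `factorAssociation()`): cross-validated probability random forest for
   the adherence label; leave-one-covariate-out importance; per-factor
   covariate-adjusted associations.
7. **Linkage** (`lipidCorrelation()`, `coxLinkage()`,
   `adherenceTertileKm()`): does predicted adherence track cholesterol
   lowering and cardiovascular hospitalization?

# Time, dates, and PDC

Claims dates are truncated to the month (a common privacy measure), so the
package works in integer month indices and converts to days at a flat
30 days/month (`DAYS_PER_MONTH`). All day quantities (follow-up, event
times, PDC denominators) inherit this resolution.

PDC is the ratio of total days of filled medication (any statin) to days of
follow-up, capped at 1. Follow-up ends at the last recorded claim of *any*
kind, which keeps the denominator honest for patients who leave the system.
Two conventions exist for overlapping fills: the literal supplied-days
ratio (early refills are banked) and the union of covered days (they are
not). We use the ratio; `computePdc()` is verified against a day-by-day
pill-consumption simulation with stockpiling, which agrees exactly, and the
test suite also carries the union-convention oracle to document where the
two differ. Whether PDC should be capped at 100% is a genuine open point;
we cap, following the convention that PDC is a proportion.

The *first-refill* variant of the adherence model adds an indicator of
whether any refill occurred and recomputes the outcome on the window that
starts when the first prescription's supply runs out (excluding the first
fill's pills), so the predictor does not trivially contain the outcome.

# Cohort filters

Filters run in a fixed order — no flagged first fill, prior statin in the
last 12 months, prior statin in the last 6 months, outside the prescribing
window, age, days supply, follow-up — and the exclusion tally is therefore
order-dependent (each patient is counted once, at the first rule that
removes them). The 12-month naïveté rule logically subsumes the 6-month
rule; both are applied and tallied separately because both appear in the
cohort definition we follow, and the 6-month tally serves as a check that
the 12-month rule did its job (it should be zero).

# The count matrix and its container

`buildCountMatrix()` counts each code's occurrences in the 6 months up to
and including the threshold month. Six months is the window for *counts*;
raw collection windows are wider (12 months for drugs and codes, 24 for
labs) and govern the interaction-count covariates and lab recency instead.
Variables seen in fewer than `minPatients` patients are dropped: the
default is 100, which is meant for cohorts of order 10^5; desk-scale
analyses (10^3–10^4 patients) should scale it down to keep comparable
prevalence (tests use 10 at n ≈ 2000). The matrix lives in a
`ClaimCountMatrix` (a `SummarizedExperiment` of variables × patients with
the variable kind in `rowData`), so standard Bioconductor accessors apply.

# Nonnegative matrix factorization

`fitNmf()` minimises squared Frobenius reconstruction error with the
classic multiplicative updates, from a seeded random-uniform
initialisation, recording the objective each iteration (the trace is
checked to be non-increasing in the tests). Numerical choices:

* tolerance `tol = 1e-5` relative objective change, `maxIter = 500`;
* `nStarts` restarts (default 1): multiplicative updates only find local
  optima, and on small cohorts a factor can collapse onto a dense nuisance
  direction; restarts with derived seeds, keeping the lowest final error,
  are the standard guard. Recovery experiments use 3–5 starts.
* loading columns are normalised to unit L2 norm after fitting (scale moves
  into the scores), and the final scores are recomputed by nonnegative
  least squares against the fixed loadings — the same routine
  `scorePatients()` uses — so in-sample re-scoring reproduces the fitted
  scores exactly;
* `log1p` transformation and row/column pre-normalisation are available but
  off by default: the object being factorized is the count matrix itself.
  Whether the rows or columns should be pre-scaled is genuinely open; we
  default to none and expose both.

`topLoadings()` ranks variables within each factor (ties broken
lexicographically, zero loadings never listed); only count variables enter
the factorization — lab *values* and prior PDC stay as direct covariates.
K = 30 is the default operating point for claim panels of a few hundred to
a few thousand variables; no automatic rank selection is attempted.

# Disease risk: borrowing strength across rare outcomes

Hospitalizations for MI, stroke, CAD and kidney disease within one year are
individually rare but related. `fitDiseaseRisk()` fits all four jointly:
each outcome's logistic coefficients are a shared mean plus an
outcome-specific deviation, with a ridge penalty on the deviations and a
weak ridge (1% of the deviation penalty) on the mean. As the deviation
penalty grows the outcomes coalesce onto one model; as both penalties
vanish the fit approaches independent logistic regressions — both limits
are verified numerically in the tests. The deviation penalty is chosen by
nested 5-fold cross-validation on multi-outcome log-loss inside each
training fold, over a deliberately small warm-started grid (default 0.5,
5, 50) so that 30-fold outer cross-validation stays affordable. An outcome
with no positive cases in a training fold simply shrinks to the shared
mean; nothing fails. The composite risk is `1 - prod(1 - p_g)`, the
probability of any event, and is the single risk covariate passed
downstream. A Cox-based risk model was considered out of scope: the joint
binary model is the stated design, and the 3-year label variant is
available via the outcome table's `eventWithin1yr`/`timeDays` columns.

# Adherence model

A probability random forest (ranger) predicts PDC > 80% under 30-fold
patient-level cross-validation; all reported discrimination is on pooled
out-of-fold probabilities (the rank-statistic c-statistic, which the tests
verify equals trapezoidal ROC integration to 1e-10). Defaults: 500 trees,
`sqrt(p)` variables per split, seeded and single-threaded for
reproducibility. `minNodeSize` is exposed because larger terminal nodes
give smoother probability estimates, which measurably improves *ranking*
when the signal is weak and smooth; the default is ranger's.

Missing numeric features (labs, prior PDC) are imputed with the
training-fold median plus a missingness-indicator column — claims data are
missing not at random, and the indicator lets the forest use missingness
itself.

Variable importance is leave-one-covariate-out with a *full* refit of the
cross-validated pipeline (same folds), not permutation importance: it
answers "what does the model lose when this information is truly absent",
and supports grouped withholding so a factor's columns move as one unit.

`factorAssociation()` is the inferential complement: one logistic
regression per factor score, adjusted for all patient/statin covariates
and the composite disease risk, reporting the coefficient sign and Wald p.

# Linkage to clinical outcomes

Predicted adherence (the out-of-fold probability, on its natural 0–1
scale) is correlated with the magnitude of cholesterol lowering (positive
r = more lowering; the raw-delta correlation is also emitted), and enters
Cox proportional-hazards models per diagnosis group and for the composite
(MI/stroke/CAD), adjusted for patient/statin covariates and predicted
disease risk. Breslow tie handling is used because month-truncated times
are heavily tied; the implementation is cross-checked in the tests against
a direct partial-likelihood maximisation on toy data. Tertiles of
predicted adherence are used only for Kaplan–Meier display and log-rank
tests, never for estimation.

# The synthetic generator

`simulateEhr()` produces data with exactly the structure the pipeline
assumes, plus the ground truth needed for parameter-recovery tests:

* latent nonnegative patient intensities θ (gamma) and a block-structured
  nonnegative loading matrix generate Poisson claim counts, so the count
  matrix has true nonnegative rank ≤ `nLatentFactors`;
* monthly refills are Bernoulli with a logistic propensity in named
  covariates (age, tobacco, latent factors); the default coefficients give
  roughly one adherent patient in ten, matching the rate typical of strict
  PDC > 80% definitions;
* optionally (`pDiscontinue`), a covariate-independent fraction of patients
  discontinues after the first fill (residual 0.5% monthly refill rate).
  This is unobserved heterogeneity — no baseline model can predict it, but
  the realized first refill reveals it, which is precisely the mechanism
  that makes a first-refill indicator add discrimination beyond baseline
  covariates. The default is 0 so that the refill mechanism stays a pure
  per-patient Bernoulli (and the closed-form correlation calibration stays
  exact); first-refill experiments and the acceptance pipeline run switch
  it on (0.15-0.25);
* LDL and total cholesterol drop by `lipidEffect` mg/dL per unit realized
  adherence (default 40, a typical moderate-intensity statin response from
  a baseline near 150 mg/dL), with 12 mg/dL measurement noise;
  `lipidEffectForCorrelation()` inverts this model in closed form when an
  experiment needs a prescribed population correlation;
* each diagnosis group has an exponential event clock whose hazard is
  `eventBaseHazard * exp(coefficients · θ + adherenceEventCoefficient ·
  adherence)` (default base hazard 2e-5/day ≈ 3.5% per group over five
  years, adherence log-hazard −0.3);
* a wellness-visit code every 6 months pins every patient's follow-up
  window; scheduled lipid panels at months 0/+3/+12 guarantee the
  cholesterol outcome is computable (`lipidPanels = FALSE` removes them
  for factor-recovery experiments, where their constant column is a
  non-latent component);
* a small fraction of patients violate each inclusion rule
  (`pPriorStatin`, `pBadDaysSupply`, ages beyond 65) so the filters are
  exercised.

What the generator does **not** emulate — and what passing tests therefore
do not establish about real claims: real coding vocabularies and their
hierarchies, seasonal and secular utilisation trends, informative censoring
correlated with health status, day-level fill timing, dose changes and
therapy switches with different supplies, measurement batch effects, and
non-adherence that is primary (never filling at all). Recovery results here
show the *machinery* is correct, not that real EHR signal is this clean.

# Problem sizes

The test suite and the acceptance script run the pipeline at desk scale,
chosen to make every property measurable in minutes on one core: full
pipeline at 4000 patients (K = 30, 30 folds), factor recovery at 2000
patients × 300 variables × 5 latent factors, forest calibration at 2000
patients, correlation recovery at 10 000, and Cox recovery at 20 000
patients × 20 replicates. The prevalence filter scales with cohort size as
noted above. All randomness flows from explicit seeds; two runs with the
same configuration are bit-identical.

# Known limitations

* 30 days/month day arithmetic biases PDC denominators slightly for long
  follow-ups; with month-truncated sources there is no better rule.
* The supplied-days PDC cannot distinguish stockpiling from consumption.
* The strength-borrowing risk model shrinks toward a single shared mean;
  with outcome clusters of genuinely different aetiology a grouped prior
  would be better.
* Leave-one-covariate-out importance is expensive (p + 1 full
  cross-validated fits) and correlated predictors share credit.
* The linkage stage conditions on estimated quantities (predicted
  adherence and risk) without propagating their uncertainty into the Cox
  standard errors.
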
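# ehrAdherence

Modelling secondary medication non-adherence from longitudinal
health-claims data, built around statin initiation.

Roughly half of patients prescribed a statin stop refilling it within a
year. A health system that could predict, at the time of the first fill,
who will not adhere could target its adherence interventions. This package
implements a complete, tested pipeline for that problem using only the
data a claims system already holds — pharmacy fills, laboratory results,
and diagnostic/procedure codes, all with month-truncated dates:

1. **Cohort construction** — treatment-naive adults (18–65) with a flagged
   first statin fill of standard duration (30/60/90/180 days supply) and at
   least a year of follow-up; per-rule exclusion tally.
2. **Feature engineering** — pre-treatment claim-count matrix (a
   `SummarizedExperiment` subclass), most-recent lab values, prior percent
   days covered (PDC) for other medications, utilisation counts.
3. **Dimension reduction** — non-negative matrix factorization
   `X ≈ S Lᵀ` (multiplicative updates, squared-Frobenius objective) of the
   count matrix into K nonnegative factors with per-patient factor scores.
4. **Outcomes** — PDC = (total days of statin supplied) / (days of
   follow-up), capped at 1; the adherence label PDC > 80%; cholesterol
   change around initiation; time-to-hospitalization per diagnosis group
   (MI, stroke, CAD, kidney disease).
5. **Disease risk** — a strength-borrowing multi-outcome penalized
   logistic model: per-outcome coefficients β_g = μ + δ_g with ridge
   penalties on the deviations δ_g and (weakly) on the shared mean μ,
   fitted under 30-fold cross-validation with nested hyperparameter
   selection; the composite risk 1 − ∏(1 − p_g) becomes a covariate.
6. **Adherence prediction** — a cross-validated probability random forest;
   the c-statistic is the Mann–Whitney rank statistic on pooled
   out-of-fold probabilities; leave-one-covariate-out ΔAUC importance;
   per-factor covariate-adjusted logistic associations.
7. **Linkage** — Pearson correlation of predicted adherence with
   cholesterol lowering; Cox proportional hazards for cardiovascular
   hospitalization adjusted for covariates and predicted risk;
   Kaplan–Meier curves by adherence tertile with log-rank tests.

A synthetic claims generator (`simulateEhr()`) with recorded ground truth
(latent phenotype intensities, true refill propensities, true hazard
multipliers) makes every stage testable by parameter recovery, without any
real patient data.

## Worked example

```r
library(ehrAdherence)

sim <- simulateEhr(simConfig(nPatients = 2000, pDiscontinue = 0.15, seed = 42))
res <- runPipeline(sim$claims, sim$demographics, K = 10, nFolds = 10,
                   minPatients = 10, numTrees = 200, seed = 42)
print(res)
```

```
ehrAdherence pipeline run (seed 42)
  cohort: 1752 of 2000 patients; adherent 8.6%
  predictors: 253 count variables -> 10 factors
  CV c-statistic: risk-only 0.705; with first refill 0.700
```

1752 of 2000 simulated patients survive the filters; the tally shows who
was removed and why (20 had a statin fill in the prior year, 211 were
outside 18–65, 17 had a non-standard days supply):

```r
res$tally
#> noFirstStatin priorStatin12mo  priorStatin6mo   outsideWindow   age  daysSupply  followup
#>             0              20               0               0   211          17         0
```

About 8.6% of the cohort clears the strict PDC > 80% bar, and the
cross-validated c-statistic of 0.705 says the baseline model ranks a
random adherent patient above a random non-adherent one about 70% of the
time. Higher predicted adherence goes with more LDL lowering:

```r
res$summary$lipidCorrelation
#>   analyte    n          r       pValue   rRawDelta
#> 1 LAB_LDL 1752 0.08477639 0.0003818199 -0.08477639
#> 2  LAB_TC 1752 0.08160602 0.0006284229 -0.08160602
```

The per-group Cox hazard ratios are also computed
(`res$summary$hazardRatios`), but with only ~50–160 events per group at
this cohort size the per-unit estimates are wide; the acceptance script
below runs the event linkage at 20 000 patients where the protective
effect is measurable.

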
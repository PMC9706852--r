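---
title: "Polyepigenetic exposure signatures: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polyepigenetic exposure signatures: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(episig)
```

## The problem

Smoking and alcohol consumption leave reproducible marks on blood DNA
methylation. A *polyepigenetic signature* is a weighted linear combination
of methylation levels at a small set of CpG sites, fitted so that it
discriminates exposed from unexposed individuals; once fitted, it serves as
an objective exposure biomarker in cohorts where self-report is unreliable
or absent, and can itself be tested as a predictor of disease and
mortality. `episig` implements the full construction-and-validation
pipeline and a synthetic-cohort generator that makes every stage testable.

## Measurement scale

Array methylation arrives as beta values $\beta \in [0,1]$ (methylated
intensity fraction per probe). All modelling happens on the logit scale,
$M = \log(\beta/(1-\beta))$, which is unbounded and closer to Gaussian.
`beta_to_mvalue()` uses the natural log by default and offers base 2 (the
common "M-value" convention); the choice only rescales coefficients.
Beta values at machine 0/1 are clipped to $[\varepsilon, 1-\varepsilon]$
with $\varepsilon = 10^{-6}$ before the transform — degenerate values occur
in simulation and the logit diverges there; with clipping disabled they are
an error.

## Preprocessing contract

- **Call-rate QC.** Samples with fewer than 95% of probes observed are
  excluded (`qc_call_rate()`, threshold configurable; the boundary value is
  retained). The call rate is computed on the matrix as given — when two
  array generations are merged, apply `intersect_arrays()` first so the
  rate refers to the shared probe set.
- **Array intersection.** Cohorts typed on 450K-style and EPIC-style chips
  are restricted to the sorted intersection of probe IDs, in identical row
  order, before any joint analysis.
- **Imputation.** "Nearest-average" imputation is implemented as
  k-nearest-row averaging: the distance between two probe rows is the
  root-mean-square difference over jointly observed samples, and a missing
  entry is the mean of the $k$ (default 10) nearest rows observed at that
  sample. The per-column normalization lets rows with different
  missingness patterns compete as neighbours; at realistic cohort sizes
  essentially no row is complete, so requiring fully observed neighbours
  would be unusable. This is a single deterministic completion, not a
  multiple-imputation draw; the uncertainty it ignores is negligible at
  the missingness rates the QC step admits (< 5% per sample).
- **Normalization** of raw intensities (dye bias, background) is upstream
  of this package and represented only by a pass-through hook that warns,
  so provenance stays visible in logs.

## Candidate pool and mQTL screen

Candidate CpGs enter as a table of literature results; a record is retained
when its source p-value clears the Bonferroni level *of the study it came
from*, $p < \alpha / n_{\text{tests}}$ with $\alpha = 0.05$
(`filter_bonferroni()`). Genetic confounding is handled by a
methylation-QTL screen (`screen_mqtl()`): for each candidate CpG–SNP pair,
ordinary least squares of the M-value on additive dosage (0/1/2); a pair
enters the map when the slope p-value is below $\alpha/n_{\text{pairs}}$
(Bonferroni across tested pairs, switchable), and only the strongest SNP
per CpG is kept (smallest p, ties by lexicographic SNP id). Monomorphic
SNPs are skipped with a warning. The test and threshold are declared
defaults — the screen's provenance literature does not fix them — and the
type-I error of the screen is verified by simulation in the test suite.

## The randomized BIC search

The exposure outcome is binary: current smokers (1) versus never smokers
(0), past smokers excluded from training but scored afterwards; or
drinkers ($\ge 1$ unit/week) versus non-drinkers. The search draws
`n_models` distinct random subsets of exactly seven pool CpGs (duplicates
redrawn, capped at 10× oversampling), attaches each included CpG's mQTL
SNP as an extra predictor, and fits each specification by
maximum-likelihood logistic regression. Fits that fail to converge or show
(quasi-)separation — detected via the fitted-probability warning or a
coefficient magnitude above 15 — are flagged and excluded from selection,
keeping the criterion comparable across specifications; exactly collinear
predictors are dropped with a warning.

Selection minimizes $\mathrm{BIC} = k\ln(n) - 2\ln\hat L$; ties break
toward fewer predictors, then lexicographic CpG ids, so the whole search
is a pure function of (pool, data, seed, `n_models`). The winner is then
pruned by backward elimination: while any predictor's Wald p-value exceeds
0.05, the worst one is dropped and the model refitted. Pruning is why
final signatures carry fewer than seven CpGs. The raw score of the final
model, $S = b_0 + \sum_j b_j M_j$, is standardized by its training-set
mean and SD, so downstream effect sizes are "per 1 SD of signature".

**Defaults.** `n_models` defaults to 10,000: with a pool of a few hundred
CpGs and seven draws per model, each CpG is missed by a single model with
probability $1 - 7/p$, so 10,000 models cover every candidate with near
certainty (for $p = 300$: $P(\text{miss}) \approx (1-0.023)^{10^4}
\approx 10^{-102}$).

**Winner's curse.** Because the minimum-BIC model is the best of
thousands, the non-causal CpGs it contains are exactly those with the
luckiest chance associations, so they survive Wald pruning at well above
the nominal 5% rate. In the package's reference recovery experiment
(60-CpG pool, 5 causal CpGs at 1.5 noise-SDs, n = 2000, 5000 models) the
pruned signature contains at least three causal CpGs essentially always
and is free of SNPs offered with zero true effect, but is a *pure* subset
of the causal set in only roughly three quarters of replicates — one
lucky noise CpG survives in the remainder. This is a
property of BIC-selection-then-pruning itself, not of the implementation;
a held-out pruning sample would remove it at the cost of training data.

## Validation statistics

- **McFadden pseudo-R²**: $1 - \ln\hat L_1 / \ln\hat L_0$ with an
  intercept-only null by default; a covariate-only null is available via
  `null = "covariates"` when the increment over the adjustment set is the
  quantity of interest.
- **AUC**: concordance of case–control score pairs (ties ½), equal to the
  scaled Mann–Whitney statistic; DeLong 95% CI by default, seeded
  stratified bootstrap optional. Verified exactly against exhaustive pair
  enumeration.
- **Continuous alcohol**: ordinary least squares of weekly units on the
  signature plus age and sex, reported as adjusted R².
- **Disease association**: logistic regression of CVD history on the
  standardized signature plus covariates; OR per 1 SD with Wald CI.
  Diagnostics: maximum Cook's distance, variance-inflation factors
  (computed as $1/(1-R_j^2)$ on the design matrix), and a linearity check
  comparing exposure-quartile indicators against the linear term by
  likelihood ratio (2 df); the check is skipped when the exposure has too
  few distinct values to bin.
- **IPW**: availability of epigenetic data is modelled by logistic
  regression; available samples are weighted by $1/\hat\pi$. Weighted
  fits use a quasibinomial family (identical point estimates, no
  non-integer-weight warnings); the model-based CI ignores weight
  estimation and is reported as such. Optional percentile truncation
  guards against extreme weights.
- **Fixed-effect sensitivity**: centre or family indicators added to the
  disease model; groups with a constant outcome across more than one
  member are dropped (their indicators would separate).

## Survival models

Time-on-study is the time scale with entry age as a covariate. All-cause
Cox models use Efron tie handling; proportionality is checked by
scaled-Schoenfeld tests (`cox.zph`, KM transform) per covariate plus a
global test. When proportionality or linearity is in doubt, the signature
term is refit with a 3-df penalized spline and compared against the linear
fit by likelihood ratio on the effective degrees of freedom.

Competing risks follow the two-absorbing-state structure — the cause of
interest versus death from any other cause — implemented as
**cause-specific hazards**: other-cause deaths are censored at the death
time, and the fit for each cause is bit-identical to an all-cause fit on
the recoded data (a tested invariant). A Fine–Gray subdistribution model
is deliberately not implemented: the two-absorbing-state transition
structure identifies the cause-specific hazard, and the reported
"subhazard ratios" are flagged as cause-specific in all outputs.

## The synthetic-cohort generator

`sim_config()` / `generate_cohort()` emulate a mid-size European
population cohort: age 52.5 (SD 15.5) years, BMI 25.6 (SD 4.7) kg/m²,
~25% current and ~33% past smokers, ~30% non-drinkers with
gamma-distributed weekly units among drinkers (shape 1.2, scale 7.5,
shifted past the 1-unit threshold), ~20% CVD prevalence, ~68% availability
of epigenetic data, three recruitment centres and family clusters.
Exposure effects are additive on the M-value scale — full `effect_size_m`
for current smokers, half for past smokers, drinker shift plus a small
per-unit dose term for alcohol — so the inverse logit keeps beta strictly
inside (0,1). A configurable fraction of pool CpGs carries a SNP (MAF
drawn in 0.1–0.5) shifting methylation per allele.

Disease and death depend on the *causal methylation burden*: the noiseless
mean M-shift at causal CpGs, z-scored across the cohort. CVD follows a
logistic model in the burden (default log-OR = ln 1.3 per SD); each cause
of death has an exponential cause-specific hazard
$\lambda_c \exp(\theta_c \cdot \text{burden})$ with the lung-cancer effect
ln 2 and other causes null by default — constant baselines give closed-form
truth for recovery tests. Availability follows a logistic selection model
on age, sex and smoking, with an optional CVD-history coefficient: only
when selection depends on the outcome as well as the exposure does the
available-subset analysis become biased, which is the regime used to test
that inverse-probability weighting removes the bias.

Where no study conditions were published — per-CpG effect sizes on the
methylation scale in particular are not reported anywhere — defaults were
chosen once for testability (effects large enough that power and recovery
are near-deterministic at the stated sample sizes) and are stated here
rather than tuned. The generator deliberately omits cell-type
composition, batch/chip effects and family correlation in methylation;
passing tests therefore demonstrate correctness of the estimators and the
search under the stated data-generating process, not robustness to those
real-data complications.

## Problem sizes and numerical choices

The test suite runs its Monte-Carlo checks at sizes chosen so each claim
is decisive yet the whole suite stays lightweight: calibration checks use
200 replicate null data sets (1000 pairs for the mQTL screen) against
99% binomial acceptance bands around the nominal 5%; estimator-recovery
checks use 25–50 replicate cohorts of n = 1000–2000; the reference
feature-recovery experiment uses 20 seeds at the full stated size
(n = 2000, 60 CpGs, 5000 models). The acceptance script rebuilds both
signatures at n = 1000 with 3000 models. Seeds control every random draw;
identical configurations yield digest-identical pipeline artifacts.

Degenerate inputs are contracts, not surprises: a probe missing in every
sample, an outcome with one class, a monomorphic SNP, zero shared samples,
an empty probe intersection, non-positive follow-up times and pruning that
empties a model each raise (or warn and skip) with messages naming the
offending object.

## Known limitations

- Single deterministic imputation; no propagation of imputation
  uncertainty.
- The winner's-curse effect on pruned signatures described above.
- IPW confidence intervals are model-based and ignore weight estimation.
- Cause-specific (not subdistribution) hazards; cumulative-incidence
  estimation is out of scope.
- The generator's independence assumptions (covariates, exposures) are
  stronger than real cohorts; confounding is available only through the
  explicit configuration hooks (age→smoking, selection→CVD).
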
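# episig

Construction and validation of **polyepigenetic exposure signatures** —
weighted combinations of blood DNA methylation levels at a handful of CpG
sites that act as objective biomarkers of tobacco and alcohol consumption —
together with the downstream epidemiology used to validate such signatures
against disease and mortality outcomes.

Self-reported smoking and drinking are noisy and biased; methylation at
exposure-responsive CpGs (e.g. the AHRR locus for smoking) records the
exposure biologically. `episig` implements the full analysis path:

1. **Preprocessing** — sample call-rate QC (95% rule), harmonization of
   450K/EPIC-style probe sets to their intersection, nearest-average
   (k-nearest-row) imputation of missing probes, and the logit transform
   from beta values to M-values: `M = log(β / (1 − β))`.
2. **Candidate pooling** — ingestion of literature-derived candidate CpGs
   with Bonferroni retention (`p < α / n_tests`), and a methylation-QTL
   screen (per-pair OLS of M-value on 0/1/2 SNP dosage) that attaches
   genetic confounders to candidate CpGs.
3. **Signature search** — the core algorithm: draw thousands of random
   combinations of seven candidate CpGs (each bringing its mQTL SNP when it
   has one), fit a maximum-likelihood logistic model of the binary exposure
   (current vs never smoker; drinker vs non-drinker) on each, pick the fit
   minimizing `BIC = k·ln(n) − 2·lnL̂`, then backward-eliminate predictors
   with Wald `p > 0.05`. The surviving model, with the training-set mean μ
   and SD σ of its linear score, is the deployable signature; scores are
   reported per training-set SD, `z = (S − μ)/σ`.
4. **Validation** — McFadden pseudo-R² (`1 − lnL̂₁/lnL̂₀`), AUC with DeLong
   95% CI, adjusted R² against weekly alcohol units, logistic CVD
   association per 1 SD with Cook's-distance / VIF / linearity diagnostics,
   inverse-probability weighting for differential availability of
   epigenetic data, and group fixed-effect sensitivity analyses.
5. **Mortality** — Cox proportional-hazards models (Efron ties) with
   scaled-Schoenfeld proportionality tests, a 3-df penalized-spline
   fallback for nonlinearity, and cause-specific competing-risk models
   (two absorbing states: the cause of interest vs all other causes).
6. **Synthetic cohorts** — a seeded generator producing phenotype tables,
   beta matrices, SNP dosages and ground truth with the joint structure the
   analysis assumes, so every estimator can be calibrated and every claim
   tested end to end without access-restricted cohort data.

## Worked example

```r
library(episig)

sim <- generate_cohort(sim_config(n_samples = 400, n_cpgs_pool = 60, seed = 7))
mv  <- beta_to_mvalue(impute_nearest_average(qc_call_rate(sim$methylation)$matrix))

model <- build_signature(mv, sim$genotypes, sim$cohort, "smoking",
                         pool_cpgs = rownames(mv), n_models = 500, seed = 3)
print(model)
#> polyepigenetic signature [smoking]: 4 CpG(s), 0 SNP(s)
#>   intercept -12.2513, score mu -3.0061 sigma 5.5597
#>   cg43940991  +2.0558
#>   cg44448591  +0.5908
#>   cg50370701  +1.7900
#>   cg72700264  +2.3172

scores <- score_samples(model, mv)
validate_signature(sim$cohort, scores, "smoking")$comparisons$smoker_vs_never
#> $mcfadden_r2  0.753
#> $auc          0.982   (95% CI 0.969-0.995)

z <- scores$standardized[match(sim$cohort$id, scores$sample_id)]
cox_all_cause(sim$cohort, z)
#> all-cause: HR per 1 SD = 1.137 (95% CI 0.939-1.377), 131 events / 400
competing_risks(sim$cohort, z)$lung_cancer
#> cause-specific [lung_cancer]: HR per 1 SD = 2.288 (95% CI 1.431-3.658), 25 events / 400
```

Three of the four selected CpGs here are true causal probes of the
simulation; the standardized signature separates smokers from never-smokers
almost perfectly (AUC 0.98) and carries the simulated lung-cancer hazard
(the generator ties lung-cancer mortality, but not other causes, to the
causal methylation burden).

The staged pipeline — simulate → preprocess → candidates → build →
validate → survival — is available as one call (`run_pipeline(config,
outdir)`), writes every artifact as plain text plus a digest manifest, and
has a thin command-line wrapper at `inst/scripts/episig.R`.

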
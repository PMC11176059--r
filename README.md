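# trionurture

Decomposing parental polygenic-score associations with child outcomes into
**genetic transmission** and **genetic nurture**, using genotyped
mother–father–child trios and a latent-factor structural model over ordinal
questionnaire items.

## The problem and who this is for

A parent's polygenic score (PGS) can predict their child's conduct problems
for two very different reasons: the parent transmitted half of the scored
alleles to the child (*genetic transmission*), or the parent's genetic
propensities shaped the environment the child grows up in (*genetic
nurture*). Distinguishing the two matters for whether parental traits are
intervention targets. Trio designs separate them: jointly modelling the
child's and both parents' scores, the association routed through the child's
own score is transmission, and the residual parental path is nurture.

This package is for statistical geneticists and epidemiologists who want
that decomposition as a reproducible, tested pipeline — including a
synthetic trio-cohort generator with known ground truth, since the real
cohorts this design needs are access-restricted.

## The model

A latent conduct-problems factor `CP` is measured by eight ordinal items
(loadings `λ_j`, thresholds `τ`), and regressed on the trio's standardized
scores:

```
Y*_j  = λ_j·CP + ε_j              (items; delta-scaled, Var(Y*_j) = 1)
CP    = β_C·PGS_C + β_M·PGS_M + β_F·PGS_F + ζ      (Var(CP) = 1)
PGS_C = a_M·PGS_M + a_F·PGS_F + δ,   cov(PGS_M, PGS_F) free
```

* direct genetic effect: `β_C`
* genetic transmission (per parent): `a_P × β_C` (≈ `0.5 × β_C` under
  random mating, because parent–child score correlations are ~0.5)
* genetic nurture (per parent): `β_M`, `β_F`
* sum rule: transmission + nurture = the unadjusted parental association

Estimation is two-step weighted least squares on the mixed correlation
matrix (polychoric among items, polyserial item × score, Pearson among
scores), with family-bootstrap or influence-function (sandwich) standard
errors, and Benjamini–Hochberg correction within declared test families.

## A worked example

```r
library(trionurture)

cfg <- sim_config(n_trios = 5000, n_variants = 200,
                  beta_child = 0.14, beta_mother = 0.03, seed = 424)
cohort <- simulate_trio_cohort(cfg)

mm <- mixed_matrix(cohort$items, cohort$scores[c("child", "mother", "father")])
ordinal_alpha(mm)
#> [1] 0.887

fit <- fit_trio_sem(mm, specify_trio_model(variant = "trio"), se = "linearized")
fit
#> <trio_sem_fit> variant = trio, n = 5000, F_min = 0.00412, df = 41
#>   CFI = 1.000, TLI = 1.000, RMSEA = 0.000, SRMR = 0.009
#> beta_c beta_m beta_f    a_m    a_f cov_mf
#> 0.1441 0.0107 0.0246 0.4943 0.5094 0.0088

transmission_effect(fit, "mother")
#>   parent effect_type  estimate     se ci_low ci_high        p
#> 1 mother transmission   0.0712 0.0109 0.0499  0.0925 5.86e-11
nurture_effect(fit, "mother")
#>   parent effect_type estimate     se  ci_low ci_high     p
#> 1 mother nurture       0.0107 0.0192 -0.0269  0.0482 0.577
```

The cohort was generated with a true direct effect of 0.14 and a true
maternal nurture effect of 0.03. The fit recovers the direct effect
(0.144), the parent-to-child score path sits at its Mendelian value
(≈ 0.5), transmission is half the direct effect (0.071), and the small
nurture effect is — as the power analysis below predicts — not
distinguishable from zero at this sample size.

Ordinal reliability of the simulated scale (`α = 0.887`) lands in the range
reported for real conduct-problem item sets, and the one-factor measurement
model fits cleanly (CFI ≈ 1, RMSEA ≈ 0).

Power planning for a study design:

```r
sc <- power_scenario(n_trios = 15477, effect_grid = c(0.02, 0.03, 0.05),
                     target = "nurture", family_size = 26, replicates = 100)
res <- run_power(sc)
autoplot(res)
```

A full simulate → score → measure → fit → decompose run is driven by a YAML
config via `run_pipeline("config.yaml")` (see `validate_config()`), or from
a shell through `inst/scripts/trionurture.R`.

## Package layout

| Area | Functions |
| --- | --- |
| simulator | `sim_config()`, `simulate_trio_cohort()`, `simulate_parents()`, `mendelian_transmit()`, `liability_to_items()`, `apply_missingness()`, `write_cohort()` |
| scoring | `gwas_inclusion_filter()`, `qc_summary_stats()`, `compute_pgs()`, `residualize_standardize()`, `filter_relatedness()` |
| measurement | `recode_collapse()`, `estimate_thresholds()`, `polychoric()`, `polyserial()`, `mixed_matrix()`, `ordinal_alpha()` |
| model | `specify_trio_model()`, `implied_moments()`, `fit_trio_sem()`, `fit_indices()`, `tidy()`, `glance()` |
| decomposition | `transmission_effect()`, `nurture_effect()`, `sum_check()`, `fdr_adjust()`, `build_report()` |
| power | `power_scenario()`, `run_power()`, `summarize_power()`, `power_analytic()` |
| orchestration | `validate_config()`, `run_pipeline()` |

The methods vignette (`vignettes/trio-nurture-methods.Rmd`) documents the
model, the simulator's scope, and every numerical design choice.
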
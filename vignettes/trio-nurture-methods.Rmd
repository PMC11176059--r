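---
title: "Decomposing parental polygenic-score associations: model, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing parental polygenic-score associations: model, simulator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trionurture)
```

## The scientific problem

Parental characteristics predict children's conduct problems, but an
association between a *parental* polygenic score (PGS) and a *child* outcome
confounds two causal routes. Because each parent transmits half of their
alleles, a parental score proxies the child's own score: part of the
association is **genetic transmission**, acting through the child's genotype.
The remainder — the association left after conditioning on the child's score —
is **genetic nurture**: parental genetic propensities expressed as rearing
environment (though assortative mating and residual population stratification
can masquerade as nurture, which is why the simulator generates both).

Genotyped mother–father–child trios identify the two routes. `trionurture`
implements the full analysis as a tested pipeline: a trio-cohort simulator
with known ground truth, polygenic scoring with summary-statistic QC, an
ordinal measurement stage, a latent-factor trio structural equation model
(SEM), the transmission/nurture decomposition with FDR control, and a
Monte-Carlo power laboratory. Because real trio cohorts of this kind are
access-restricted, every stage is validated against synthetic cohorts whose
generating parameters are known exactly.

## The model

The child outcome is a latent conduct-problems factor \(CP\) measured by
eight ordinal questionnaire items (4 categories by default). Writing
\(PGS_C, PGS_M, PGS_F\) for the standardized child/maternal/paternal scores
of one trait:

\[
\begin{aligned}
Y^*_j &= \lambda_j\, CP + \varepsilon_j, \qquad
  Y_j = k \iff \tau_{j,k-1} < Y^*_j \le \tau_{j,k},\\
CP &= \beta_C\, PGS_C + \beta_M\, PGS_M + \beta_F\, PGS_F + \zeta,\\
PGS_C &= a_M\, PGS_M + a_F\, PGS_F + \delta, \qquad
  \mathrm{cov}(PGS_M, PGS_F) \text{ free.}
\end{aligned}
\]

All observed and latent variables are kept on the unit-variance scale: the
latent item responses \(Y^*_j\) have unit variance (delta parameterization)
and the latent factor's residual variance is implied by the constraint
\(\mathrm{Var}(CP) = 1\) rather than estimated as a separate free parameter.
This is a one-to-one reparameterization of the same implied correlation
structure that makes every reported coefficient *already* standardized — the
solution one would otherwise obtain by rescaling afterwards.

The decomposition then reads off the fitted paths:

* **direct genetic effect** — \(\beta_C\);
* **genetic transmission** (per parent) — \(a_P \times \beta_C\), the
  association routed through the transmitted alleles. Under random mating
  \(a_P \approx 0.5\), so transmission is effectively half the direct effect;
* **genetic nurture** (per parent) — \(\beta_M\) or \(\beta_F\), the residual
  parental path;
* **sum rule** — transmission plus nurture equals the *unadjusted*
  (population) association between the parental score and the outcome,
  estimated from a one-score model. The pipeline reports the difference as a
  consistency diagnostic; on complete data it is below 0.01 in absolute
  value.

## Estimation

Fitting is two-step, the standard approach for ordinal SEM:

1. **Stage one** (`mixed_matrix()`): item thresholds from marginal
   cumulative-probit proportions; polychoric correlations among items and
   polyserial correlations between items and scores by maximum likelihood
   with thresholds fixed (two-step ML, Brent search with tolerance 1e-6,
   rectangle probabilities from a Genz-quadrature bivariate-normal CDF
   accurate to ~1e-15); Pearson correlations among scores. Listwise complete
   cases define the fitted sample by default (pairwise deletion is an
   option), matching the usual practice of fitting the measurement model on
   children with complete item data.
2. **Stage two** (`fit_trio_sem()`): minimize
   \(\sum_k w_k\,(s_k - \sigma_k(\theta))^2\) over the 55 non-redundant
   correlations by bounded quasi-Newton (L-BFGS-B, numerical gradients,
   convergence factor 1e4 × machine epsilon, iteration cap 1000). Weights
   are identity (ULS, default) or inverse estimated sampling variances of
   the stage-one correlations (DWLS). Point estimates are consistent under
   either; DWLS mainly reweights. Data-driven starting values (loadings from
   the item block, structural paths by solving the score block) make the
   optimum reproducible; `n_starts` random restarts verify unimodality, and
   the gradient at the optimum is checked below 1e-5 in the test suite.

Model fit is summarized by the nominal WLS statistic \(T = (n-1)F_{min}\)
and CFI/TLI/RMSEA/SRMR against the independence baseline. Because the ULS
\(T\) is not calibrated as a chi-square, these indices are descriptive here;
mean/variance-corrected statistics are out of scope and flagged as such.

### Uncertainty

Two standard-error paths are provided, with different roles:

* **Family bootstrap** (default for reporting): resample trios with
  replacement, recompute stage one and the fit per replicate; SEs are
  replicate SDs, intervals are percentile intervals, p-values use the
  bootstrap-normal z statistic. Replicate failures are logged and more than
  10% of them abort the analysis. This is assumption-light and its coverage
  is verified by simulation in the test suite.
* **Linearized (influence-function sandwich)**: the asymptotic covariance of
  the stage-one correlations is estimated from per-observation influence
  functions — including the propagated influence of the estimated
  thresholds — and pushed through the WLS estimator by the delta method.
  This costs one extra pass over the data instead of hundreds of refits,
  which is what makes the 100-replicate power scenarios tractable; its
  calibration is verified by a 400-replicate null simulation (type-I error
  within [0.03, 0.07] at nominal 5%).

Transmission being a product of two estimates, its SE comes from the
replicate distribution of the product (bootstrap) or the delta method
(linearized).

### Multiple testing

Trait-by-trait analyses are corrected by Benjamini–Hochberg within declared
families — in a 13-trait analysis, 13 transmission tests and 26 nurture
tests (one per parent) — with significance at \(q < 0.05\). `fdr_adjust()`
accepts a family size larger than the vector supplied so that staged
reporting still adjusts against the full family.

## The simulator: what it emulates, and what it does not

`simulate_trio_cohort()` reproduces the statistical structure the analysis
assumes, with every effect known:

* **Genotypes**: independent biallelic variants, frequencies uniform on
  `maf_range` (default [0.05, 0.5]); children receive one allele per parent
  (a heterozygous parent transmits either allele with probability 0.5). This
  yields the parent–child score correlation of ~0.5 that transmission
  estimates lean on.
* **Scores**: true per-variant weights drawn once per cohort; raw scores are
  weighted allele sums, standardized in-sample.
* **Liability and items**: \(CP\) built from the configured
  \(\beta_C, \beta_M, \beta_F\) with residual variance completing unit
  variance; items generated from loadings (default 0.7) and thresholds
  (default 0, 0.84, 1.64, i.e. marginal category probabilities
  0.50/0.30/0.15/0.05 — the right-skew typical of conduct items).
* **Assortative mating**: couples matched by score rank against a noisy
  key whose correlation with the paternal score equals the target spousal
  correlation; comonotone matching then transfers that correlation to the
  couple. Simple, seed-stable, and checked against its own target.
* **Stratification**: discrete subpopulations with Balding–Nichols
  frequency drift and a liability offset — the minimal structure that makes
  nurture paths spuriously nonzero unless scores are residualized on
  ancestry covariates.
* **Missingness**: MCAR, or MAR with missingness logistic in a covariate
  (intercept solved so the marginal rate is exact); the real mechanism
  behind ~50% questionnaire missingness is unknown, so both options are
  explicit knobs rather than claims.

Deliberately **not** emulated: linkage disequilibrium, chromosome structure,
sex chromosomes, item-specific rater effects, and correlated item residuals
(the measurement model assumes none). Passing tests therefore demonstrate
that the estimators recover the generating process *of this structure*; they
do not certify behavior under LD-induced weight miscalibration or
measurement non-invariance.

## Numerical and design choices

* **Tie-break in relatedness filtering**: when two families share a close
  cross-family relative (IBD proportion > 0.1768), the family whose ID sorts
  later is removed. Any fixed rule works; determinism is the point.
* **Allele alignment in scoring**: dosages counted on the other allele are
  flipped (d → 2 − d); allele pairs matching neither orientation are dropped
  and logged, never strand-corrected, since strand-ambiguous variants are
  already excluded by QC.
* **Degenerate inputs**: items with an empty internal category raise a
  collapse-advising error; a score exactly linear in covariates raises a
  zero-variance error rather than returning standardized noise; rank
  deficiency in covariates names the collinear columns.
* **Power-lab test families**: non-target family members are null by
  design, so their p-values are drawn i.i.d. uniform rather than simulated
  through 12–25 additional cohort fits per replicate — exactly their null
  distribution under independent, well-calibrated tests (the calibration is
  itself verified).
* **Problem sizes**: simulation-backed checks use the sizes at which their
  tolerances are meaningful — n = 20,000 for stage-one bias bounds
  (±0.02), n = 15,000 for the transmission/direct ratio (±0.04),
  n = 15,477 with 100 replicates for the power scenarios, 400 null
  replicates at n = 2,000 for test calibration, and 25 outer replicates of
  a 50-draw bootstrap at n = 1,200 for interval coverage. Stratification
  contrasts average five cohorts, because the realized score-ancestry
  confounding under random drift varies across cohort draws. Power scenarios
  default to 200 variants: once scores are standardized, the score-level
  correlation structure the SEM consumes does not depend on the variant
  count, and 500-variant cohorts are reserved for the score-correlation
  checks themselves.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_trios = 5000, n_variants = 200,
                  beta_child = 0.14, beta_mother = 0.03, seed = 424)
cohort <- simulate_trio_cohort(cfg)

mm <- mixed_matrix(cohort$items, cohort$scores[c("child", "mother", "father")])
ordinal_alpha(mm)

fit <- fit_trio_sem(mm, specify_trio_model(variant = "trio"),
                    se = "bootstrap", B = 200, seed = 1)
tidy(fit)
glance(fit)

transmission_effect(fit, "mother")
nurture_effect(fit, "mother")

unadj <- fit_trio_sem(mm, specify_trio_model(variant = "unadjusted_mother"),
                      se = "bootstrap", B = 200, seed = 1)
sum_check(fit, unadj)
```

For power planning:

```{r power, eval = FALSE}
sc <- power_scenario(n_trios = 15477, effect_grid = c(0.02, 0.03, 0.05),
                     target = "nurture", family_size = 26, replicates = 100)
res <- run_power(sc)
autoplot(res)
```

## Known limitations

* The ULS/DWLS test statistic is uncorrected; fit indices are descriptive.
* Missing item data are handled by listwise (or pairwise) deletion, not
  full-information estimation or multiple imputation; under covariate-driven
  missingness the fitted subsample can differ from the cohort.
* The multi-trait sensitivity model frees all parental-score covariances and
  child-score residual covariances; with many traits the parameter count
  grows quadratically and fitting slows accordingly.
* Nurture estimates absorb whatever assortative mating and stratification
  the covariates fail to remove — by design, since that is the quantity the
  trio model identifies.
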
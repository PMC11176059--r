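# Shared fixtures, built in code. Expensive fits are cached per session.

.fixture_env <- new.env(parent = emptyenv())

# A moderate cohort with known paths plus trio/unadjusted bootstrap fits,
# reused by the semcore recovery and decomp tests.
recovery_fixture <- function() {
  if (!is.null(.fixture_env$recovery)) return(.fixture_env$recovery)
  cfg <- sim_config(n_trios = 5000, n_variants = 150, beta_child = 0.14,
                    beta_mother = 0.03, seed = 424)
  cohort <- simulate_trio_cohort(cfg, keep_genotypes = FALSE)
  mm <- mixed_matrix(cohort$items, cohort$scores[c("child", "mother", "father")])
  spec <- specify_trio_model(variant = "trio")
  trio <- fit_trio_sem(mm, spec, se = "bootstrap", B = 60, seed = 99)
  unadj_m <- fit_trio_sem(mm, specify_trio_model(variant = "unadjusted_mother"),
                          se = "bootstrap", B = 60, seed = 99)
  .fixture_env$recovery <- list(cfg = cfg, cohort = cohort, mm = mm,
                                spec = spec, trio = trio, unadj_m = unadj_m)
  .fixture_env$recovery
}

# Mixed-correlation container built from an exact model-implied matrix
# (population moments, no sampling error), for exact-recovery tests.
implied_mixed_cor <- function(spec, theta, n = 10000) {
  R <- implied_moments(spec, theta)
  structure(list(R = R, type = NULL, n_pair = NULL, thresholds = NULL,
                 item_labels = spec$items,
                 score_labels = setdiff(spec$labels, spec$items),
                 n = n, policy = "listwise", items = NULL, scores = NULL,
                 fingerprint = c(n = n, items = 0, scores = 0)),
            class = "mixed_cor")
}

# Reference trio parameter vector used across exact-fit tests.
theta_ref <- function() {
  c(setNames(rep(0.7, 8), paste0("lambda_item", 1:8)),
    beta_c = 0.14, beta_m = 0.03, beta_f = 0, a_m = 0.5, a_f = 0.5,
    cov_mf = 0)
}

# Draw correlated ordinal pairs directly from the latent bivariate normal —
# an oracle generator independent of the package's simulation chain.
draw_ordinal_pair <- function(n, rho, tau_x, tau_y) {
  z1 <- rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  list(x = 1L + findInterval(z1, tau_x), y = 1L + findInterval(z2, tau_y))
}
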
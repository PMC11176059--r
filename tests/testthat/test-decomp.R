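test_that("transmission is the product of the a path and the direct effect", {
  spec <- specify_trio_model(variant = "trio")
  mm <- implied_mixed_cor(spec, theta_ref(), n = 15000)
  fit <- fit_trio_sem(mm, spec)
  tr <- transmission_effect(fit, "mother")
  expect_equal(tr$estimate, 0.5 * 0.14, tolerance = 1e-4)
  expect_equal(transmission_effect(fit, "average")$estimate, 0.5 * 0.14,
               tolerance = 1e-4)

  # beta_c = 0 forces zero transmission whatever the a paths
  theta0 <- theta_ref(); theta0["beta_c"] <- 0
  fit0 <- fit_trio_sem(implied_mixed_cor(spec, theta0), spec)
  expect_equal(transmission_effect(fit0, "mother")$estimate, 0, tolerance = 1e-4)

  nu <- nurture_effect(fit, "mother")
  expect_equal(nu$estimate, 0.03, tolerance = 1e-4)
  expect_error(transmission_effect(fit0, "aunt"))
})

test_that("recovery simulation brackets the true transmission effect", {
  fx <- recovery_fixture()
  tr <- transmission_effect(fx$trio, "mother")  # truth: 0.5 * 0.14 = 0.07
  expect_lt(abs(tr$estimate - 0.07), 3 * tr$se)
  expect_true(tr$ci_low <= 0.07 && 0.07 <= tr$ci_high)
  expect_lt(tr$p, 0.001)
})

test_that("transmission + nurture equals the unadjusted parental association", {
  fx <- recovery_fixture()
  sc <- sum_check(fx$trio, fx$unadj_m)
  expect_lt(abs(sc$difference), 0.01)
  expect_true(is.finite(sc$ci_low) && is.finite(sc$ci_high))

  # different data must be refused
  other <- simulate_trio_cohort(sim_config(n_trios = 500, n_variants = 60,
                                           seed = 5150), keep_genotypes = FALSE)
  mm_o <- mixed_matrix(other$items, other$scores[c("child", "mother", "father")])
  f_o <- fit_trio_sem(mm_o, specify_trio_model(variant = "unadjusted_mother"))
  expect_error(sum_check(fx$trio, f_o), class = "trionurture_consistency_error")
  expect_error(sum_check(fx$trio, fx$trio))
})

test_that("adjusted and unadjusted child effects agree without indirect paths", {
  co <- simulate_trio_cohort(sim_config(n_trios = 8000, n_variants = 150,
                                        beta_child = 0.14, seed = 515),
                             keep_genotypes = FALSE)
  mm <- mixed_matrix(co$items, co$scores[c("child", "mother", "father")])
  f_trio <- fit_trio_sem(mm, specify_trio_model(variant = "trio"))
  f_uc <- fit_trio_sem(mm, specify_trio_model(variant = "unadjusted_child"))
  expect_lt(abs(f_trio$estimates[["beta_c"]] - f_uc$estimates[["beta_child"]]),
            0.01)
})

test_that("BH adjustment matches hand computation and the step-up definition", {
  expect_equal(as.numeric(fdr_adjust(c(0.01, 0.02, 0.03, 0.04), "demo")),
               rep(0.04, 4))
  expect_equal(as.numeric(fdr_adjust(rep(1, 5), "demo")), rep(1, 5))
  expect_equal(as.numeric(fdr_adjust(0.03, "demo")), 0.03)
  expect_error(fdr_adjust(numeric(0), "demo"), class = "trionurture_config_error")
  expect_error(fdr_adjust(c(0.5, 1.2), "demo"), class = "trionurture_config_error")

  # brute-force step-up oracle: q_(i) = min over j >= i of p_(j) * m / j
  bh_oracle <- function(p, m = length(p)) {
    o <- order(p)
    q_sorted <- pmin(rev(cummin(rev(sort(p) * m / seq_along(p)))), 1)
    out <- numeric(length(p)); out[o] <- q_sorted
    out
  }
  set.seed(606)
  for (rep in seq_len(1000)) {
    k <- sample(1:20, 1)
    p <- runif(k)^sample(1:3, 1)
    m <- k + sample(0:10, 1)
    q <- as.numeric(fdr_adjust(p, "oracle", m = m))
    expect_equal(q, bh_oracle(p, m), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-12))
  }
})

test_that("stratification biases nurture and covariate residualization removes it", {
  # the realized score-ancestry confounding depends on the random drift x
  # weight draw, so the contrast is averaged over five cohorts
  spec <- specify_trio_model(variant = "trio")
  bias <- vapply(1:5, function(s) {
    co <- simulate_trio_cohort(sim_config(n_trios = 4000, n_variants = 150,
                                          beta_child = 0.1, n_subpops = 2,
                                          fst = 0.1, strat_shift = 0.8,
                                          seed = s), keep_genotypes = FALSE)
    mm_raw <- mixed_matrix(co$items, co$scores[c("child", "mother", "father")])
    f_raw <- fit_trio_sem(mm_raw, spec)
    adj <- residualize_standardize(co$scores, co$covariates["subpop"])
    mm_adj <- mixed_matrix(co$items, adj[c("child", "mother", "father")])
    f_adj <- fit_trio_sem(mm_adj, spec)
    c(raw = mean(abs(f_raw$estimates[c("beta_m", "beta_f")])),
      adj = mean(abs(f_adj$estimates[c("beta_m", "beta_f")])))
  }, numeric(2))
  expect_gt(mean(bias["raw", ]), 0.04)  # spurious nurture from shared ancestry
  expect_lt(mean(bias["adj", ]), mean(bias["raw", ]) / 2)
  expect_lt(mean(bias["adj", ]), 0.05)
})

test_that("the report collates 13 traits into 13 transmission and 26 nurture rows", {
  co <- simulate_trio_cohort(sim_config(n_trios = 1200, n_variants = 80,
                                        beta_child = 0.2, seed = 707),
                             keep_genotypes = FALSE)
  mm <- mixed_matrix(co$items, co$scores[c("child", "mother", "father")])
  one_trait <- list(
    trio = fit_trio_sem(mm, specify_trio_model(variant = "trio"), se = "linearized"),
    unadjusted_child = fit_trio_sem(mm, specify_trio_model(variant = "unadjusted_child")),
    unadjusted_mother = fit_trio_sem(mm, specify_trio_model(variant = "unadjusted_mother")),
    unadjusted_father = fit_trio_sem(mm, specify_trio_model(variant = "unadjusted_father")))
  fits <- setNames(rep(list(one_trait), 13), paste0("trait", 1:13))
  rep13 <- build_report(fits, transmission_family = 13, nurture_family = 26)
  expect_equal(sum(rep13$effect_type == "transmission"), 13)
  expect_equal(sum(rep13$effect_type == "nurture"), 26)
  expect_equal(sum(rep13$effect_type == "direct"), 13)
  expect_true(all(rep13$q >= rep13$p - 1e-12, na.rm = TRUE))
  expect_equal(rep13$significant, !is.na(rep13$q) & rep13$q < 0.05)

  # round-trip through TSV
  path <- withr::local_tempfile(fileext = ".tsv")
  write_report(rep13, path)
  back <- read_report(path)
  expect_equal(back$estimate, rep13$estimate, tolerance = 1e-12)
  expect_equal(back$q, rep13$q, tolerance = 1e-12)

  # missing fits are reported, not fatal
  fits$trait1$trio <- NULL
  rep12 <- build_report(fits)
  expect_equal(sum(rep12$effect_type == "transmission"), 12)
  expect_match(attr(rep12, "incomplete"), "trait1", all = FALSE)
})
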
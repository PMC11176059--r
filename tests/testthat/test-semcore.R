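test_that("model variants carry the expected free parameters and variables", {
  trio <- specify_trio_model(variant = "trio")
  expect_length(trio$par_names, 8 + 3 + 2 + 1)  # loadings, betas, a paths, cov
  expect_length(trio$labels, 11)

  uc <- specify_trio_model(variant = "unadjusted_child")
  expect_false(any(grepl("^a_|^beta_m$|^beta_f$|^cov", uc$par_names)))
  expect_length(uc$labels, 9)

  multi <- specify_trio_model(traits = paste0("t", 1:12), variant = "multi")
  expect_length(setdiff(multi$labels, multi$items), 36)
  expect_error(specify_trio_model(variant = "nonsense"))
})

test_that("implied moments follow path tracing", {
  spec <- specify_trio_model(variant = "trio")
  theta <- theta_ref()
  theta["beta_m"] <- 0; theta["beta_f"] <- 0
  R <- implied_moments(spec, theta)
  expect_equal(R["child", "mother"], 0.5)              # a_m + a_f * cov_mf
  expect_equal(R["item1", "item2"], 0.49)              # lambda_j * lambda_k
  # corr(CP, mother) = beta_c * corr(child, mother) = 0.07, seen via items
  expect_equal(R["item1", "mother"], 0.7 * 0.5 * 0.14)
  expect_equal(R["item1", "child"], 0.7 * 0.14)

  zero <- theta; zero[] <- 0
  expect_true(all(implied_moments(spec, zero)[lower.tri(diag(11))] == 0))

  bad <- theta; bad["a_m"] <- 0.9; bad["a_f"] <- 0.9
  expect_error(implied_moments(spec, bad), class = "trionurture_inadmissible_error")
})

test_that("fitting exact population moments recovers parameters with perfect fit", {
  spec <- specify_trio_model(variant = "trio")
  theta <- theta_ref()
  mm <- implied_mixed_cor(spec, theta, n = 15000)
  fit <- fit_trio_sem(mm, spec)
  expect_lt(fit$F_min, 1e-10)
  expect_equal(unname(fit$estimates), unname(theta), tolerance = 1e-4)
  expect_lt(fit$indices$srmr, 1e-5)
  expect_equal(fit$indices$cfi, 1)
  expect_equal(fit$indices$rmsea, 0)
  expect_lt(fit$convergence$max_abs_grad, 1e-5)
})

test_that("a baseline-equal fit has CFI 0 and df = 0 leaves RMSEA undefined", {
  spec <- specify_trio_model(variant = "trio")
  theta0 <- theta_ref(); theta0[] <- 0
  mm <- implied_mixed_cor(spec, theta_ref(), n = 5000)
  # evaluate the baseline (all-zero) parameterization as if it were the fit
  fake <- structure(list(spec = spec, estimates = theta0,
                         F_min = sum(.subset2(mm, "R")[lower.tri(mm$R)]^2),
                         df = length(mm$R[lower.tri(mm$R)]),
                         n = 5000, s_obs = mm$R[lower.tri(mm$R)],
                         weights_w = rep(1, sum(lower.tri(mm$R)))),
                    class = "trio_sem_fit")
  idx <- fit_indices(fake)
  expect_equal(idx$cfi, 0)

  # saturated toy model: df = 0, RMSEA reported as missing
  sat_spec <- structure(list(
    variant = "toy", traits = "t", items = c("y1", "y2"),
    labels = c("y1", "y2", "x"), par_names = c("l1", "l2", "b"),
    lower = rep(-0.999, 3), upper = rep(0.999, 3),
    implied = function(theta) {
      R <- diag(1, 3)
      R[1, 2] <- R[2, 1] <- theta[1] * theta[2]
      R[1, 3] <- R[3, 1] <- theta[1] * theta[3]
      R[2, 3] <- R[3, 2] <- theta[2] * theta[3]
      list(R = R, pen = 0, var_cp = 1)
    }), class = "trio_sem_spec")
  R_obs <- diag(1, 3); R_obs[upper.tri(R_obs)] <- R_obs[lower.tri(R_obs)] <- c(0.3, 0.2, 0.15)
  dimnames(R_obs) <- list(c("y1", "y2", "x"), c("y1", "y2", "x"))
  mm_sat <- structure(list(R = R_obs, n = 1000, item_labels = c("y1", "y2"),
                           score_labels = "x", policy = "listwise",
                           fingerprint = c(1, 0, 0)), class = "mixed_cor")
  fit_sat <- fit_trio_sem(mm_sat, sat_spec, start = c(l1 = 0.5, l2 = 0.5, b = 0.3))
  expect_lt(fit_sat$F_min, 1e-9)
  expect_true(is.na(fit_sat$indices$rmsea))

  over_spec <- sat_spec
  over_spec$par_names <- c(over_spec$par_names, "extra")
  over_spec$lower <- c(over_spec$lower, -1); over_spec$upper <- c(over_spec$upper, 1)
  expect_error(fit_trio_sem(mm_sat, over_spec),
               class = "trionurture_identification_error")
})

test_that("ULS matches a brute-force grid search on a toy one-factor model", {
  # 3 items with a shared loading plus one continuous predictor
  toy <- structure(list(
    variant = "toy", traits = "t", items = paste0("y", 1:3),
    labels = c(paste0("y", 1:3), "x"), par_names = c("lambda", "beta"),
    lower = c(0.01, -0.99), upper = c(0.99, 0.99),
    implied = function(theta) {
      lam <- theta[1]; b <- theta[2]
      R <- diag(1, 4)
      R[1:3, 1:3] <- lam^2; diag(R) <- 1
      R[1:3, 4] <- R[4, 1:3] <- lam * b
      list(R = R, pen = 0, var_cp = 1)
    }), class = "trio_sem_spec")

  set.seed(77)
  n <- 3000
  x <- rnorm(n)
  cp <- 0.3 * x + sqrt(1 - 0.09) * rnorm(n)
  items <- tibble::as_tibble(liability_to_items(cp, loadings = rep(0.6, 8),
                                                thresholds = rep(list(0), 8))[, 1:3])
  names(items) <- paste0("y", 1:3)
  mm <- mixed_matrix(items, data.frame(x = x))
  fit <- fit_trio_sem(mm, toy)

  s_obs <- mm$R[toy$labels, toy$labels][lower.tri(diag(4))]
  grid <- expand.grid(lambda = seq(0.01, 0.99, 0.01), beta = seq(-0.99, 0.99, 0.01))
  Fg <- mapply(function(l, b) {
    sigma <- c(l^2, l^2, l * b, l^2, l * b, l * b)
    sum((s_obs - sigma)^2)
  }, grid$lambda, grid$beta)
  best <- grid[which.min(Fg), ]
  expect_lt(abs(fit$estimates[["lambda"]] - best$lambda), 0.011)
  expect_lt(abs(fit$estimates[["beta"]] - best$beta), 0.011)
})

test_that("the optimum is stable across random restarts", {
  fx <- recovery_fixture()
  fit <- fit_trio_sem(fx$mm, fx$spec, n_starts = 5)
  expect_false(fit$convergence$multimodal)
  expect_lt(diff(range(fit$convergence$optima)), 1e-8)
  expect_lt(fit$convergence$max_abs_grad, 1e-5)
})

test_that("simulated cohorts are recovered within bootstrap intervals", {
  fx <- recovery_fixture()
  truth <- c(beta_c = 0.14, beta_m = 0.03, beta_f = 0, a_m = 0.5, a_f = 0.5)
  # jointly requiring five 95% intervals to cover would fail ~1 run in 4 by
  # construction; each parameter must sit within 3.5 bootstrap SDs instead,
  # with strict interval coverage asserted for the two headline paths
  for (p in names(truth)) {
    expect_lt(abs(fx$trio$estimates[[p]] - truth[[p]]),
              3.5 * sd(fx$trio$boot[, p]))
  }
  ci <- fx$trio$ci
  expect_true(ci["beta_c", 1] <= 0.14 && 0.14 <= ci["beta_c", 2])
  expect_true(ci["beta_m", 1] <= 0.03 && 0.03 <= ci["beta_m", 2])
  expect_equal(unname(fx$trio$estimates[paste0("lambda_item", 1:8)]),
               rep(0.7, 8), tolerance = 0.05)
  expect_lte(fx$trio$boot_failures, 6)  # at most 10% of B = 60
})

test_that("the family bootstrap is seed-deterministic", {
  co <- simulate_trio_cohort(sim_config(n_trios = 800, n_variants = 80,
                                        beta_child = 0.2, seed = 83),
                             keep_genotypes = FALSE)
  mm <- mixed_matrix(co$items, co$scores[c("child", "mother", "father")])
  spec <- specify_trio_model(variant = "trio")
  f1 <- fit_trio_sem(mm, spec, se = "bootstrap", B = 50, seed = 5)
  f2 <- fit_trio_sem(mm, spec, se = "bootstrap", B = 50, seed = 5)
  expect_identical(f1$boot, f2$boot)
  expect_error(fit_trio_sem(mm, spec, se = "bootstrap", B = 20),
               class = "trionurture_config_error")
})

test_that("bootstrap intervals attain nominal coverage for the direct effect", {
  spec <- specify_trio_model(variant = "trio")
  hits <- 0L; outer <- 25L
  for (r in seq_len(outer)) {
    co <- simulate_trio_cohort(sim_config(n_trios = 1200, n_variants = 80,
                                          beta_child = 0.14, seed = 9000 + r),
                               keep_genotypes = FALSE)
    mm <- mixed_matrix(co$items, co$scores[c("child", "mother", "father")])
    fit <- fit_trio_sem(mm, spec, se = "bootstrap", B = 50, seed = r)
    if (fit$ci["beta_c", 1] <= 0.14 && 0.14 <= fit$ci["beta_c", 2]) hits <- hits + 1L
  }
  # nominal 95%; with 25 outer replicates P(hits <= 20) < 0.002 under nominal
  expect_gte(hits, 21L)
})

test_that("DWLS weighting reproduces ULS point estimates on clean data", {
  fx <- recovery_fixture()
  fit_dwls <- fit_trio_sem(fx$mm, fx$spec, estimator = "dwls")
  expect_equal(unname(fit_dwls$estimates), unname(fx$trio$estimates),
               tolerance = 0.02)
})

test_that("tidy and glance expose the fit in broom shape", {
  fx <- recovery_fixture()
  td <- tidy(fx$trio)
  expect_true(all(c("term", "estimate", "std.error", "conf.low", "conf.high")
                  %in% names(td)))
  expect_equal(nrow(td), 14)
  gl <- glance(fx$trio)
  expect_equal(gl$n, fx$mm$n)
  expect_true(gl$converged)
  expect_lt(gl$rmsea, 0.05)  # correctly specified one-factor model at large n
})
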
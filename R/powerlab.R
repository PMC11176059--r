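# Monte-Carlo power analysis for the trio decomposition tests.

#' Define a power scenario
#'
#' A scenario fixes the cohort-generating conditions, the target test
#' (transmission or nurture), the multiple-testing family, and the
#' Monte-Carlo settings. The effect grid applies to the target effect: direct
#' child effects for a transmission target, parental nurture paths for a
#' nurture target.
#'
#' @param n_trios Trios per simulated cohort.
#' @param effect_grid Target effect sizes (standardized) to scan.
#' @param target `"transmission"` or `"nurture"`.
#' @param parent Which parental path carries the target (and is tested).
#' @param beta_child Direct child effect held fixed when the target is
#'   nurture.
#' @param family_size Size of the BH test family (e.g. 13 transmission tests
#'   or 26 nurture tests in a 13-PGS analysis); the non-target members are
#'   simulated as null, i.e. their p-values are drawn i.i.d. uniform.
#' @param n_true Number of true effects in the family (the target counts as
#'   one; only the target is simulated through the model).
#' @param alpha Significance level on (adjusted) p-values.
#' @param correction `"bh"` or `"none"`.
#' @param replicates Monte-Carlo replicates per grid point (>= 50).
#' @param n_variants Variants used to simulate genotypes (the score-level
#'   correlation structure is invariant to this once scores are
#'   standardized).
#' @param loadings,thresholds Measurement model for the eight items.
#' @param measurement_bypass If `TRUE`, analyse the latent liability directly
#'   by linear regression instead of the ordinal SEM — a fast mode for
#'   analytic cross-checks, not an emulation of the questionnaire analysis.
#' @param seed Master seed; per-replicate seeds are derived from it.
#' @return A `power_scenario` list.
#' @export
power_scenario <- function(n_trios = 15477,
                           effect_grid = 0.03,
                           target = c("nurture", "transmission"),
                           parent = c("mother", "father"),
                           beta_child = 0.14,
                           family_size = 26,
                           n_true = 1,
                           alpha = 0.05,
                           correction = c("bh", "none"),
                           replicates = 100,
                           n_variants = 200,
                           loadings = rep(0.7, 8),
                           thresholds = c(0, 0.8416212, 1.6448536),
                           measurement_bypass = FALSE,
                           seed = 1L) {
  target <- match.arg(target)
  parent <- match.arg(parent)
  correction <- match.arg(correction)
  if (replicates < 50) .stop_config("power scenarios need replicates >= 50")
  if (any(effect_grid < 0)) .stop_config("effect grid values must be >= 0")
  if (n_true < 1 || n_true > family_size) {
    .stop_config("n_true must lie in [1, family_size]")
  }
  structure(list(n_trios = as.integer(n_trios), effect_grid = effect_grid,
                 target = target, parent = parent, beta_child = beta_child,
                 family_size = as.integer(family_size), n_true = as.integer(n_true),
                 alpha = alpha, correction = correction,
                 replicates = as.integer(replicates),
                 n_variants = as.integer(n_variants),
                 loadings = loadings, thresholds = thresholds,
                 measurement_bypass = measurement_bypass,
                 seed = as.integer(seed)),
            class = "power_scenario")
}

# One replicate: simulate, analyse, return the target estimate and p-value.
.power_replicate <- function(sc, effect, rep_seed, spec) {
  cfg <- sim_config(
    n_trios = sc$n_trios, n_variants = sc$n_variants,
    beta_child = if (sc$target == "transmission") effect else sc$beta_child,
    beta_mother = if (sc$target == "nurture" && sc$parent == "mother") effect else 0,
    beta_father = if (sc$target == "nurture" && sc$parent == "father") effect else 0,
    loadings = sc$loadings, thresholds = sc$thresholds, seed = rep_seed
  )
  cohort <- simulate_trio_cohort(cfg, keep_genotypes = FALSE)
  sc_cols <- c("child", "mother", "father")
  if (sc$measurement_bypass) {
    d <- cohort$scores[sc_cols]
    d$y <- cohort$liability
    m <- lm(y ~ child + mother + father, data = d)
    cm <- summary(m)$coefficients
    if (sc$target == "nurture") {
      est <- cm[sc$parent, 1]; se <- cm[sc$parent, 2]
    } else {
      a_fit <- lm(child ~ mother + father, data = d)
      a <- coef(a_fit)[[sc$parent]]
      se_a <- summary(a_fit)$coefficients[sc$parent, 2]
      bc <- cm["child", 1]; se_b <- cm["child", 2]
      est <- a * bc
      se <- sqrt(bc^2 * se_a^2 + a^2 * se_b^2)
    }
    p <- 2 * pnorm(-abs(est / se))
    return(c(estimate = est, p = p))
  }
  mm <- mixed_matrix(cohort$items, cohort$scores[sc_cols])
  fit <- fit_trio_sem(mm, spec, se = "linearized")
  eff <- if (sc$target == "nurture") {
    nurture_effect(fit, sc$parent)
  } else {
    transmission_effect(fit, sc$parent)
  }
  c(estimate = eff$estimate, p = eff$p)
}

#' Run a Monte-Carlo power scenario
#'
#' Per replicate and grid point: simulate a trio cohort, run the measurement
#' stage and the trio SEM (linearized standard errors), test the target
#' effect, apply the scenario's multiple-testing correction within the
#' declared family (non-target members drawn as null uniform p-values), and
#' record the rejection. Power is the rejection proportion with an exact
#' binomial Monte-Carlo interval.
#'
#' @param scenario A [power_scenario()].
#' @param progress Emit a message per grid point.
#' @return A `power_result` tibble: effect, power, mc_low, mc_high,
#'   mean_estimate, empirical_se, n_used, replicates; the scenario is
#'   attached as an attribute.
#' @export
run_power <- function(scenario, progress = FALSE) {
  stopifnot(inherits(scenario, "power_scenario"))
  spec <- specify_trio_model(variant = "trio")
  rows <- list()
  for (gi in seq_along(scenario$effect_grid)) {
    effect <- scenario$effect_grid[gi]
    est <- p <- rep(NA_real_, scenario$replicates)
    fails <- 0L
    for (r in seq_len(scenario$replicates)) {
      rep_seed <- .derive_seed(scenario$seed, sprintf("power_g%d_r%d", gi, r))
      out <- tryCatch(.power_replicate(scenario, effect, rep_seed, spec),
                      error = function(e) NULL)
      if (is.null(out)) fails <- fails + 1L else {
        est[r] <- out["estimate"]; p[r] <- out["p"]
      }
    }
    if (fails > 0.05 * scenario$replicates) {
      abort(sprintf("power scenario unstable: %d of %d replicates failed",
                    fails, scenario$replicates),
            class = c("trionurture_instability_error", "trionurture_error"))
    }
    ok <- !is.na(p)
    reject <- vapply(which(ok), function(r) {
      if (scenario$correction == "none") return(p[r] < scenario$alpha)
      set.seed(.derive_seed(scenario$seed, sprintf("family_g%d_r%d", gi, r)))
      fam <- c(p[r], runif(scenario$family_size - scenario$n_true))
      q <- fdr_adjust(fam, "power_family")
      q[1] < scenario$alpha
    }, logical(1))
    k <- sum(reject); nr <- sum(ok)
    ci <- binom.test(k, nr)$conf.int
    rows[[gi]] <- tibble(effect = effect, power = k / nr,
                         mc_low = ci[1], mc_high = ci[2],
                         mean_estimate = mean(est[ok]),
                         empirical_se = sd(est[ok]),
                         n_used = nr, replicates = scenario$replicates)
    if (progress) {
      message(sprintf("effect %.3f: power %.3f [%.3f, %.3f]",
                      effect, k / nr, ci[1], ci[2]))
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "scenario") <- scenario
  class(out) <- c("power_result", class(out))
  out
}

#' Summarize one or more power results
#'
#' Binds results into a long table keyed by scenario, preserving each
#' scenario's seed and test family in the metadata columns.
#'
#' @param ... `power_result` objects (or a single list of them).
#' @return Long tibble: scenario, target, parent, family_size, seed, effect,
#'   power, mc_low, mc_high, mean_estimate, empirical_se.
#' @export
summarize_power <- function(...) {
  results <- list(...)
  if (length(results) == 1 && !inherits(results[[1]], "power_result")) {
    results <- results[[1]]
  }
  nm <- names(results) %||% paste0("scenario_", seq_along(results))
  nm[nm == ""] <- paste0("scenario_", which(nm == ""))
  purrr::map2_dfr(results, nm, function(res, label) {
    sc <- attr(res, "scenario")
    dplyr::mutate(tibble::as_tibble(res),
                  scenario = label, target = sc$target, parent = sc$parent,
                  family_size = sc$family_size, correction = sc$correction,
                  n_trios = sc$n_trios, seed = sc$seed,
                  .before = 1)
  })
}

#' Analytic power for a standardized coefficient test
#'
#' Normal-approximation power for a two-sided z-test of a standardized
#' regression coefficient at sample size `n`, with the standard error
#' inflated by a variance inflation factor — 1.5 being the VIF of one
#' parent's score regressed on the child plus other-parent scores when the
#' parent-child score correlation is 0.5.
#'
#' @param n Sample size.
#' @param effect Standardized effect size.
#' @param alpha Two-sided level.
#' @param vif Variance inflation factor of the tested predictor.
#' @return Power (probability of rejection).
#' @export
power_analytic <- function(n, effect, alpha = 0.05, vif = 1.5) {
  se <- sqrt(vif / n)
  crit <- qnorm(1 - alpha / 2)
  pnorm(effect / se - crit) + pnorm(-effect / se - crit)
}
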
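# Decomposition of parental polygenic-score associations into genetic
# transmission (via the transmitted alleles: a_parent * beta_C) and genetic
# nurture (the residual parental path) components.

.fit_se_of <- function(fit, term) {
  if (!is.null(fit$se)) unname(fit$se[term]) else NA_real_
}

.fit_ci_of <- function(fit, term, est, se) {
  if (!is.null(fit$ci) && term %in% rownames(fit$ci)) {
    c(fit$ci[term, 1], fit$ci[term, 2])
  } else if (is.finite(se)) {
    c(est - 1.96 * se, est + 1.96 * se)
  } else c(NA_real_, NA_real_)
}

#' Genetic transmission effect
#'
#' The effect of a parental polygenic score on the child outcome mediated by
#' the transmitted alleles: the product `a_parent * beta_C` of the
#' parent-to-child score path and the direct child-score effect, from the
#' same trio fit. With bootstrap replicates the SE/CI come from the replicate
#' distribution of the product; with a linearized fit the delta method is
#' used; `"average"` averages the maternal and paternal products.
#'
#' @param fit A converged `trio_sem_fit` of the `"trio"` variant.
#' @param parent `"mother"`, `"father"`, or `"average"`.
#' @return One-row tibble: parent, estimate, se, ci_low, ci_high, p.
#' @export
transmission_effect <- function(fit, parent = c("mother", "father", "average")) {
  parent <- match.arg(parent)
  stopifnot(inherits(fit, "trio_sem_fit"))
  if (fit$spec$variant != "trio") .stop_config("transmission needs a trio-variant fit")
  bc <- unname(fit$estimates["beta_c"])
  a_terms <- switch(parent, mother = "a_m", father = "a_f", average = c("a_m", "a_f"))
  a <- mean(fit$estimates[a_terms])
  est <- a * bc
  se <- NA_real_; ci <- c(NA_real_, NA_real_)
  if (!is.null(fit$boot)) {
    prod_reps <- rowMeans(fit$boot[, a_terms, drop = FALSE]) * fit$boot[, "beta_c"]
    se <- sd(prod_reps)
    ci <- quantile(prod_reps, c(0.025, 0.975), names = FALSE)
  } else if (!is.null(fit$vcov)) {
    # delta method on (mean of a terms) * beta_c
    g <- setNames(numeric(length(fit$estimates)), names(fit$estimates))
    g[a_terms] <- bc / length(a_terms)
    g["beta_c"] <- a
    se <- sqrt(max(as.numeric(t(g) %*% fit$vcov %*% g), 0))
    ci <- c(est - 1.96 * se, est + 1.96 * se)
  }
  p <- if (is.finite(se) && se > 0) 2 * pnorm(-abs(est / se)) else NA_real_
  tibble(parent = parent, effect_type = "transmission",
         estimate = est, se = se, ci_low = ci[1], ci_high = ci[2], p = p)
}

#' Genetic nurture effect
#'
#' The residual association between a parental polygenic score and the child
#' outcome after conditioning on the child's own score: the direct parental
#' path (`beta_m` or `beta_f`) from the trio fit.
#'
#' @param fit A converged `trio_sem_fit` of the `"trio"` variant.
#' @param parent `"mother"` or `"father"`.
#' @return One-row tibble: parent, estimate, se, ci_low, ci_high, p.
#' @export
nurture_effect <- function(fit, parent = c("mother", "father")) {
  parent <- match.arg(parent)
  stopifnot(inherits(fit, "trio_sem_fit"))
  if (fit$spec$variant != "trio") .stop_config("nurture needs a trio-variant fit")
  term <- if (parent == "mother") "beta_m" else "beta_f"
  est <- unname(fit$estimates[term])
  se <- .fit_se_of(fit, term)
  if (!is.null(fit$boot)) se <- sd(fit$boot[, term])
  ci <- .fit_ci_of(fit, term, est, se)
  p <- if (is.finite(se) && se > 0) 2 * pnorm(-abs(est / se)) else NA_real_
  tibble(parent = parent, effect_type = "nurture",
         estimate = est, se = se, ci_low = ci[1], ci_high = ci[2], p = p)
}

#' Sum rule: transmission + nurture vs the unadjusted parental association
#'
#' On the same data, the genetic transmission effect plus the genetic nurture
#' effect from the trio model should equal the parental polygenic score's
#' unadjusted (population) association with the outcome.
#'
#' @param trio_fit Trio-variant `trio_sem_fit`.
#' @param unadj_fit The matching `unadjusted_mother` / `unadjusted_father`
#'   fit on the same data.
#' @return One-row tibble with the three components, the difference, and a
#'   bootstrap CI for the difference when both fits carry paired replicates.
#' @export
sum_check <- function(trio_fit, unadj_fit) {
  stopifnot(inherits(trio_fit, "trio_sem_fit"), inherits(unadj_fit, "trio_sem_fit"))
  variant <- unadj_fit$spec$variant
  if (!variant %in% c("unadjusted_mother", "unadjusted_father")) {
    .stop_config("unadj_fit must be an unadjusted parental fit")
  }
  if (!identical(trio_fit$mm$fingerprint, unadj_fit$mm$fingerprint)) {
    abort("fits were computed on different data (fingerprint mismatch)",
          class = c("trionurture_consistency_error", "trionurture_error"))
  }
  parent <- sub("unadjusted_", "", variant)
  tr <- transmission_effect(trio_fit, parent)
  nu <- nurture_effect(trio_fit, parent)
  unadj_term <- paste0("beta_", parent)
  unadj <- unname(unadj_fit$estimates[unadj_term])
  diff <- tr$estimate + nu$estimate - unadj
  ci <- c(NA_real_, NA_real_)
  if (!is.null(trio_fit$boot) && !is.null(unadj_fit$boot) &&
      nrow(trio_fit$boot) == nrow(unadj_fit$boot)) {
    a_term <- if (parent == "mother") "a_m" else "a_f"
    b_term <- if (parent == "mother") "beta_m" else "beta_f"
    d_reps <- trio_fit$boot[, a_term] * trio_fit$boot[, "beta_c"] +
      trio_fit$boot[, b_term] - unadj_fit$boot[, unadj_term]
    ci <- quantile(d_reps, c(0.025, 0.975), names = FALSE)
  }
  tibble(parent = parent, transmission = tr$estimate, nurture = nu$estimate,
         unadjusted = unadj, difference = diff,
         ci_low = ci[1], ci_high = ci[2])
}

#' Benjamini-Hochberg q-values within a declared test family
#'
#' Step-up FDR adjustment with monotonicity enforcement. The family size may
#' exceed the number of supplied p-values (e.g. 13 transmission tests or 26
#' nurture tests in a 13-PGS analysis reported trait by trait).
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param family Label of the test family (recorded, not used numerically).
#' @param m Family size (default `length(p)`).
#' @return Numeric q-values, same length/order as `p`.
#' @export
#' @examples
#' fdr_adjust(c(0.01, 0.02, 0.03, 0.04), "demo")  # all 0.04
fdr_adjust <- function(p, family = "tests", m = length(p)) {
  if (!length(p)) .stop_config("empty p-value family")
  if (any(!is.finite(p) | p < 0 | p > 1)) .stop_config("p-values must lie in [0, 1]")
  if (m < length(p)) .stop_config("family size m cannot be below length(p)")
  q <- p.adjust(p, method = "BH", n = m)
  attr(q, "family") <- family
  q
}

#' Build the decomposition report
#'
#' Collates trio and unadjusted fits across traits into the headline table:
#' one transmission row per trait (average of the two parental products), one
#' nurture row per trait and parent, one direct-effect row per trait, with
#' unadjusted comparisons, the sum-rule difference, BH q-values within the
#' transmission and nurture families, and significance flags at `q < 0.05`.
#'
#' @param fits Named list (one element per trait); each element is a list
#'   with components `trio` and optionally `unadjusted_child`,
#'   `unadjusted_mother`, `unadjusted_father` (all `trio_sem_fit`s).
#' @param q_threshold Significance threshold on q-values.
#' @param transmission_family,nurture_family Family sizes for the BH
#'   adjustment; default the number of rows of each type in the report.
#' @return A `decomposition_result` tibble: trait, parent, effect_type,
#'   estimate, se, ci_low, ci_high, p, q, significant, sum_difference.
#'   Traits with missing fits are listed in the `incomplete` attribute.
#' @export
build_report <- function(fits, q_threshold = 0.05,
                         transmission_family = NULL, nurture_family = NULL) {
  stopifnot(is.list(fits), !is.null(names(fits)))
  rows <- list(); incomplete <- character(0)
  for (trait in names(fits)) {
    f <- fits[[trait]]
    if (is.null(f$trio)) {
      incomplete <- c(incomplete, paste0(trait, ": missing trio fit"))
      next
    }
    tr <- transmission_effect(f$trio, "average")
    rows[[length(rows) + 1]] <- dplyr::mutate(tr, trait = trait, parent = "both")
    direct <- tibble(
      trait = trait, parent = "child", effect_type = "direct",
      estimate = unname(f$trio$estimates["beta_c"]),
      se = if (!is.null(f$trio$boot)) sd(f$trio$boot[, "beta_c"]) else
        .fit_se_of(f$trio, "beta_c"))
    direct$ci_low <- .fit_ci_of(f$trio, "beta_c", direct$estimate, direct$se)[1]
    direct$ci_high <- .fit_ci_of(f$trio, "beta_c", direct$estimate, direct$se)[2]
    direct$p <- if (is.finite(direct$se) && direct$se > 0)
      2 * pnorm(-abs(direct$estimate / direct$se)) else NA_real_
    rows[[length(rows) + 1]] <- direct
    for (parent in c("mother", "father")) {
      nu <- nurture_effect(f$trio, parent)
      nu$trait <- trait
      unadj_name <- paste0("unadjusted_", parent)
      if (!is.null(f[[unadj_name]])) {
        sc <- sum_check(f$trio, f[[unadj_name]])
        nu$unadjusted <- sc$unadjusted
        nu$sum_difference <- sc$difference
      } else {
        incomplete <- c(incomplete, paste0(trait, ": missing ", unadj_name))
      }
      rows[[length(rows) + 1]] <- nu
    }
    if (!is.null(f$unadjusted_child)) {
      rows[[length(rows) + 1]] <- tibble(
        trait = trait, parent = "child", effect_type = "unadjusted_child",
        estimate = unname(f$unadjusted_child$estimates["beta_child"]))
    }
  }
  out <- dplyr::bind_rows(rows)
  out <- dplyr::relocate(out, "trait", "parent", "effect_type")
  out$q <- NA_real_
  tr_idx <- which(out$effect_type == "transmission" & is.finite(out$p))
  nu_idx <- which(out$effect_type == "nurture" & is.finite(out$p))
  if (length(tr_idx)) {
    out$q[tr_idx] <- fdr_adjust(out$p[tr_idx], "transmission",
                                m = transmission_family %||% length(tr_idx))
  }
  if (length(nu_idx)) {
    out$q[nu_idx] <- fdr_adjust(out$p[nu_idx], "nurture",
                                m = nurture_family %||% length(nu_idx))
  }
  out$significant <- !is.na(out$q) & out$q < q_threshold
  attr(out, "incomplete") <- incomplete
  class(out) <- c("decomposition_result", class(out))
  out
}

#' Write / read a decomposition report as TSV
#'
#' @param report A `decomposition_result` (or any tibble).
#' @param path File path.
#' @return `write_report`: the path, invisibly. `read_report`: the tibble.
#' @export
write_report <- function(report, path) {
  readr::write_tsv(as.data.frame(report), path)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
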
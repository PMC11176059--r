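# Trio structural equation model on a mixed correlation matrix.
#
# All variables are standardized (scores z-scored in-sample, latent item
# responses on the delta scale, latent conduct-problems factor constrained to
# unit variance), so every free parameter is already on the standardized
# scale and the estimates form the standardized solution.

#' Specify a trio structural model
#'
#' Builds the parameter map and model-implied-moment function for one of the
#' model variants: the single-trait trio model (items load on a latent
#' conduct-problems factor; the factor is regressed on child, maternal and
#' paternal polygenic scores; the child score is regressed on both parental
#' scores, whose covariance is free), the unadjusted one-score-at-a-time
#' models, or the multi-trait sensitivity model (the same structure
#' replicated per trait with free covariances among parental scores and among
#' child-score residuals).
#'
#' @param traits Character vector of trait labels (length 1 unless
#'   `variant = "multi"`).
#' @param variant One of `"trio"`, `"unadjusted_child"`,
#'   `"unadjusted_mother"`, `"unadjusted_father"`, `"multi"`.
#' @param items Item labels (default `item1..item8`).
#' @param score_labels For the single-trait variants, the column names of the
#'   child/mother/father scores in the data (default
#'   `c("child", "mother", "father")`). For `"multi"`, labels are built as
#'   `<role>_<trait>`.
#' @return A `trio_sem_spec` object.
#' @export
specify_trio_model <- function(traits = "pgs",
                               variant = c("trio", "unadjusted_child",
                                           "unadjusted_mother",
                                           "unadjusted_father", "multi"),
                               items = paste0("item", 1:8),
                               score_labels = c("child", "mother", "father")) {
  variant <- match.arg(variant)
  ni <- length(items)
  lam_names <- paste0("lambda_", items)
  lam_lo <- rep(-0.999, ni); lam_hi <- rep(0.999, ni)

  if (variant %in% c("unadjusted_child", "unadjusted_mother", "unadjusted_father")) {
    role <- sub("unadjusted_", "", variant)
    sc <- score_labels[[match(role, c("child", "mother", "father"))]]
    par_names <- c(lam_names, paste0("beta_", role))
    implied <- function(theta) {
      lam <- theta[seq_len(ni)]; beta <- theta[ni + 1]
      p <- ni + 1
      R <- diag(1, p)
      R[seq_len(ni), seq_len(ni)] <- tcrossprod(lam); diag(R) <- 1
      R[seq_len(ni), p] <- R[p, seq_len(ni)] <- lam * beta
      list(R = R, pen = max(0, beta^2 - 1), var_cp = 1)
    }
    labels <- c(items, sc)
    lower <- c(lam_lo, -0.999); upper <- c(lam_hi, 0.999)
  } else if (variant == "trio") {
    sc <- score_labels
    par_names <- c(lam_names, "beta_c", "beta_m", "beta_f", "a_m", "a_f", "cov_mf")
    implied <- function(theta) {
      lam <- theta[seq_len(ni)]
      bc <- theta[ni + 1]; bm <- theta[ni + 2]; bf <- theta[ni + 3]
      am <- theta[ni + 4]; af <- theta[ni + 5]; cmf <- theta[ni + 6]
      vC <- 1 - (am^2 + af^2 + 2 * am * af * cmf)
      S <- matrix(c(1, am + af * cmf, af + am * cmf,
                    am + af * cmf, 1, cmf,
                    af + am * cmf, cmf, 1), 3, 3)
      b <- c(bc, bm, bf)
      expl <- as.numeric(t(b) %*% S %*% b)
      cov_cp <- as.numeric(S %*% b)
      p <- ni + 3
      R <- diag(1, p)
      R[seq_len(ni), seq_len(ni)] <- tcrossprod(lam); diag(R) <- 1
      R[seq_len(ni), ni + 1:3] <- outer(lam, cov_cp)
      R[ni + 1:3, seq_len(ni)] <- t(R[seq_len(ni), ni + 1:3])
      R[ni + 1:3, ni + 1:3] <- S
      list(R = R, pen = max(0, -vC) + max(0, expl - 1), var_cp = 1)
    }
    labels <- c(items, sc)
    lower <- c(lam_lo, rep(-0.999, 6)); upper <- c(lam_hi, rep(0.999, 6))
  } else { # multi
    Tn <- length(traits)
    if (Tn < 2) .stop_config("multi variant needs at least 2 traits")
    child_l <- paste0("child_", traits)
    mother_l <- paste0("mother_", traits)
    father_l <- paste0("father_", traits)
    parent_l <- c(mother_l, father_l)
    np <- 2 * Tn
    pc_pairs <- which(upper.tri(diag(np)), arr.ind = TRUE)
    ce_pairs <- which(upper.tri(diag(Tn)), arr.ind = TRUE)
    par_names <- c(lam_names,
                   paste0("beta_c_", traits), paste0("beta_m_", traits),
                   paste0("beta_f_", traits),
                   paste0("a_m_", traits), paste0("a_f_", traits),
                   paste0("cov_", parent_l[pc_pairs[, 1]], "_", parent_l[pc_pairs[, 2]]),
                   if (Tn > 1) paste0("rcov_", child_l[ce_pairs[, 1]], "_",
                                      child_l[ce_pairs[, 2]]))
    implied <- function(theta) {
      i <- ni
      lam <- theta[seq_len(ni)]
      bc <- theta[i + seq_len(Tn)]; i <- i + Tn
      bm <- theta[i + seq_len(Tn)]; i <- i + Tn
      bf <- theta[i + seq_len(Tn)]; i <- i + Tn
      am <- theta[i + seq_len(Tn)]; i <- i + Tn
      af <- theta[i + seq_len(Tn)]; i <- i + Tn
      Sp <- diag(1, np)
      for (r in seq_len(nrow(pc_pairs))) {
        Sp[pc_pairs[r, 1], pc_pairs[r, 2]] <- Sp[pc_pairs[r, 2], pc_pairs[r, 1]] <-
          theta[i + r]
      }
      i <- i + nrow(pc_pairs)
      E <- matrix(0, Tn, Tn)
      for (r in seq_len(nrow(ce_pairs))) {
        E[ce_pairs[r, 1], ce_pairs[r, 2]] <- E[ce_pairs[r, 2], ce_pairs[r, 1]] <-
          theta[i + r]
      }
      A <- matrix(0, Tn, np)
      for (t in seq_len(Tn)) { A[t, t] <- am[t]; A[t, Tn + t] <- af[t] }
      Scp <- A %*% Sp               # cov(child scores, parent scores)
      Scc <- A %*% Sp %*% t(A) + E  # child-child, diagonal completed below
      vres <- 1 - diag(Scc)
      diag(Scc) <- 1
      # score covariance in order child, mother, father
      S <- rbind(cbind(Scc, Scp), cbind(t(Scp), Sp))
      b <- c(bc, bm, bf)
      expl <- as.numeric(t(b) %*% S %*% b)
      cov_cp <- as.numeric(S %*% b)
      nsc <- Tn + np
      p <- ni + nsc
      R <- diag(1, p)
      R[seq_len(ni), seq_len(ni)] <- tcrossprod(lam); diag(R) <- 1
      R[seq_len(ni), ni + seq_len(nsc)] <- outer(lam, cov_cp)
      R[ni + seq_len(nsc), seq_len(ni)] <- t(R[seq_len(ni), ni + seq_len(nsc)])
      R[ni + seq_len(nsc), ni + seq_len(nsc)] <- S
      pen <- sum(pmax(0, -vres)) + max(0, expl - 1)
      ev_min <- min(eigen(Sp, symmetric = TRUE, only.values = TRUE)$values)
      pen <- pen + max(0, -ev_min)
      list(R = R, pen = pen, var_cp = 1)
    }
    labels <- c(items, child_l, mother_l, father_l)
    nfree <- length(par_names)
    lower <- rep(-0.999, nfree); lower[seq_len(ni)] <- -0.999
    upper <- rep(0.999, nfree)
  }
  structure(list(variant = variant, traits = traits, items = items,
                 labels = labels, par_names = par_names,
                 lower = lower, upper = upper, implied = implied),
            class = "trio_sem_spec")
}

#' @export
print.trio_sem_spec <- function(x, ...) {
  cat(sprintf("<trio_sem_spec> variant = %s, %d variables, %d free parameters\n",
              x$variant, length(x$labels), length(x$par_names)))
  invisible(x)
}

#' Model-implied correlations
#'
#' Evaluates the model-implied correlation matrix at a parameter vector.
#'
#' @param spec A [specify_trio_model()] spec.
#' @param theta Named (or positionally ordered) parameter vector.
#' @return Implied correlation matrix with variable labels.
#' @export
implied_moments <- function(spec, theta) {
  stopifnot(inherits(spec, "trio_sem_spec"))
  theta <- .order_theta(spec, theta)
  imp <- spec$implied(theta)
  if (imp$pen > 1e-10) {
    abort("parameters imply an inadmissible solution (variance out of range)",
          class = c("trionurture_inadmissible_error", "trionurture_error"))
  }
  dimnames(imp$R) <- list(spec$labels, spec$labels)
  imp$R
}

.order_theta <- function(spec, theta) {
  if (!is.null(names(theta)) && all(spec$par_names %in% names(theta))) {
    theta <- theta[spec$par_names]
  }
  if (length(theta) != length(spec$par_names)) {
    .stop_config("theta length does not match the spec's free parameters")
  }
  as.numeric(theta)
}

.vech_off <- function(R) R[lower.tri(R)]

# Data-driven starting values for the optimizer.
.start_values <- function(spec, R) {
  if (!spec$variant %in% c("trio", "unadjusted_child", "unadjusted_mother",
                           "unadjusted_father", "multi")) {
    # custom spec: neutral interior start
    return(setNames(pmin(pmax(0.2, spec$lower + 1e-3), spec$upper - 1e-3),
                    spec$par_names))
  }
  ni <- length(spec$items)
  Ri <- R[seq_len(ni), seq_len(ni)]
  off <- Ri[lower.tri(Ri)]
  lbar <- sqrt(max(mean(off), 0.04))
  lam <- vapply(seq_len(ni), function(j) {
    min(max(mean(Ri[j, -j]) / lbar, 0.05), 0.95)
  }, numeric(1))
  theta <- setNames(numeric(length(spec$par_names)), spec$par_names)
  theta[seq_len(ni)] <- lam
  sc_idx <- ni + seq_len(length(spec$labels) - ni)
  if (spec$variant == "trio") {
    S <- R[sc_idx, sc_idx]
    cmf <- S[2, 3]
    a <- tryCatch(solve(matrix(c(1, cmf, cmf, 1), 2), c(S[1, 2], S[1, 3])),
                  error = function(e) c(0.5, 0.5))
    g <- vapply(seq_along(sc_idx), function(k) {
      mean(R[seq_len(ni), sc_idx[k]] / lam)
    }, numeric(1))
    b <- tryCatch(as.numeric(solve(S, g)), error = function(e) rep(0, 3))
    theta[c("beta_c", "beta_m", "beta_f")] <- pmin(pmax(b, -0.9), 0.9)
    theta[c("a_m", "a_f")] <- pmin(pmax(a, -0.9), 0.9)
    theta["cov_mf"] <- cmf
  } else if (spec$variant %in% c("unadjusted_child", "unadjusted_mother",
                                 "unadjusted_father")) {
    g <- mean(R[seq_len(ni), sc_idx[1]] / lam)
    theta[ni + 1] <- min(max(g, -0.9), 0.9)
  } else {
    Tn <- length(spec$traits)
    S <- R[sc_idx, sc_idx]
    g <- vapply(seq_along(sc_idx), function(k) {
      mean(R[seq_len(ni), sc_idx[k]] / lam)
    }, numeric(1))
    b <- tryCatch(as.numeric(solve(S + diag(1e-6, nrow(S)), g)),
                  error = function(e) rep(0, length(sc_idx)))
    theta[ni + seq_len(3 * Tn)] <- pmin(pmax(b, -0.9), 0.9)
    for (t in seq_len(Tn)) {
      theta[paste0("a_m_", spec$traits[t])] <- S[t, Tn + t]
      theta[paste0("a_f_", spec$traits[t])] <- S[t, 2 * Tn + t]
    }
    # parental covariances straight from the observed block
    pl <- c(paste0("mother_", spec$traits), paste0("father_", spec$traits))
    Sp_obs <- R[pl, pl]
    ut <- which(upper.tri(Sp_obs), arr.ind = TRUE)
    nm <- paste0("cov_", pl[ut[, 1]], "_", pl[ut[, 2]])
    theta[nm] <- Sp_obs[upper.tri(Sp_obs)] * 0.9
  }
  theta
}

.num_jacobian <- function(f, x, h = 1e-6) {
  f0 <- f(x)
  J <- matrix(0, length(f0), length(x))
  for (j in seq_along(x)) {
    xp <- x; xm <- x
    xp[j] <- x[j] + h; xm[j] <- x[j] - h
    J[, j] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}

.num_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(j) {
    xp <- x; xm <- x
    xp[j] <- x[j] + h; xm[j] <- x[j] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

#' Fit the trio structural model by weighted least squares
#'
#' Minimizes the diagonal-weight discrepancy
#' `sum(w * (s - sigma(theta))^2)` between the stage-one correlations `s`
#' and the model-implied correlations, with identity weights (ULS, default)
#' or inverse estimated sampling variances of the stage-one correlations
#' (DWLS). Standard errors are optional: `"linearized"` uses an
#' influence-function sandwich for the asymptotic covariance of the
#' stage-one correlations; `"bootstrap"` resamples families.
#'
#' @param mm A [mixed_matrix()] object.
#' @param spec A [specify_trio_model()] spec (variable labels must match the
#'   mixed matrix).
#' @param estimator `"uls"` or `"dwls"`.
#' @param se `"none"`, `"linearized"`, or `"bootstrap"`.
#' @param B Bootstrap replicates (when `se = "bootstrap"`).
#' @param seed Seed for the bootstrap resampling.
#' @param start Optional named start vector.
#' @param n_starts Number of additional random admissible starts; the best
#'   optimum is kept and multimodality (differing optima) is recorded.
#' @return A `trio_sem_fit` object.
#' @export
fit_trio_sem <- function(mm, spec, estimator = c("uls", "dwls"),
                         se = c("none", "linearized", "bootstrap"),
                         B = 200, seed = 1L, start = NULL, n_starts = 0) {
  estimator <- match.arg(estimator)
  se <- match.arg(se)
  stopifnot(inherits(mm, "mixed_cor"), inherits(spec, "trio_sem_spec"))
  miss <- setdiff(spec$labels, colnames(mm$R))
  if (length(miss)) {
    .stop_config(paste0("mixed matrix lacks variables: ",
                        paste(miss, collapse = ", ")))
  }
  R_obs <- mm$R[spec$labels, spec$labels]
  s_obs <- .vech_off(R_obs)
  nmom <- length(s_obs)
  nfree <- length(spec$par_names)
  df <- nmom - nfree
  if (df < 0) {
    abort("model has more free parameters than fitted moments",
          class = c("trionurture_identification_error", "trionurture_error"))
  }

  Gamma <- NULL
  if (estimator == "dwls" || se == "linearized") {
    Gamma <- .stage_one_acov(mm, spec$labels)
  }
  w <- if (estimator == "dwls") {
    1 / pmax(diag(Gamma), 1e-10)
  } else rep(1, nmom)

  objective <- function(theta) {
    imp <- spec$implied(theta)
    sum(w * (s_obs - .vech_off(imp$R))^2) + 100 * imp$pen
  }

  run_opt <- function(th0) {
    optim(th0, objective, method = "L-BFGS-B",
          lower = spec$lower, upper = spec$upper,
          control = list(maxit = 1000, factr = 1e4))
  }

  th0 <- if (is.null(start)) .start_values(spec, R_obs) else .order_theta(spec, start)
  best <- run_opt(th0)
  optima <- best$value
  if (n_starts > 0) {
    old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    set.seed(.derive_seed(seed, "multistart"))
    for (r in seq_len(n_starts)) {
      jitter <- th0 + rnorm(nfree, 0, 0.1)
      jitter <- pmin(pmax(jitter, spec$lower + 1e-3), spec$upper - 1e-3)
      cand <- tryCatch(run_opt(jitter), error = function(e) NULL)
      if (!is.null(cand)) {
        optima <- c(optima, cand$value)
        if (cand$value < best$value - 1e-12) best <- cand
      }
    }
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
  }
  theta_hat <- setNames(best$par, spec$par_names)
  F_min <- best$value
  grad <- .num_grad(objective, best$par)
  conv <- list(code = best$convergence, counts = best$counts,
               max_abs_grad = max(abs(grad)),
               multimodal = length(unique(round(optima, 8))) > 1,
               optima = optima)
  if (best$convergence != 0) {
    warn(sprintf("optimizer returned convergence code %d: %s",
                 best$convergence, best$message %||% ""))
  }

  fit <- structure(list(
    spec = spec, estimates = theta_hat, F_min = F_min, df = df,
    n = mm$n, s_obs = s_obs, weights_w = w,
    estimator = estimator, se_method = se, convergence = conv,
    R_obs = R_obs, mm = mm
  ), class = "trio_sem_fit")

  fit$indices <- fit_indices(fit)

  if (se == "linearized") {
    Delta <- .num_jacobian(function(th) .vech_off(spec$implied(th)$R), best$par)
    WD <- Delta * w
    bread <- tryCatch(solve(t(Delta) %*% WD), error = function(e) NULL)
    if (is.null(bread)) {
      warn("singular information matrix; linearized SEs unavailable")
    } else {
      meat <- t(WD) %*% (Gamma %*% WD)
      V <- bread %*% meat %*% bread
      fit$vcov <- (V + t(V)) / 2
      dimnames(fit$vcov) <- list(spec$par_names, spec$par_names)
      fit$se <- sqrt(pmax(diag(fit$vcov), 0))
    }
  } else if (se == "bootstrap") {
    boot <- .bootstrap_replicates(mm, spec, estimator, B, seed, theta_hat)
    fit$boot <- boot$replicates
    fit$boot_failures <- boot$failures
    fit$se <- apply(boot$replicates, 2, sd)
    fit$ci <- t(apply(boot$replicates, 2, quantile, c(0.025, 0.975), na.rm = TRUE))
  }
  fit
}

# Asymptotic covariance (avar of the estimates, i.e. cov(s) itself) of the
# stage-one correlations via per-observation influence functions. The
# two-step structure is accounted for: each correlation's influence function
# carries the propagated influence of the marginal threshold estimates
# (tau_k = qnorm(F_k), so IF(tau_k) = (1{y <= k} - F_k) / dnorm(tau_k)).
.stage_one_acov <- function(mm, labels) {
  n <- mm$n
  p <- length(labels)
  il <- intersect(labels, mm$item_labels)
  get_var <- function(lbl) {
    if (lbl %in% mm$item_labels) mm$items[, lbl] else mm$scores[, lbl]
  }
  # threshold influence functions per item, cached
  tau_if <- list()
  for (lbl in il) {
    v <- get_var(lbl)
    tau <- mm$thresholds[[lbl]]
    lev <- sort(unique(v))
    Fk <- cumsum(tabulate(match(v, lev), length(lev)))[-length(lev)] / n
    tau_if[[lbl]] <- vapply(seq_along(tau), function(k) {
      ((v <= lev[k]) - Fk[k]) / dnorm(tau[k])
    }, numeric(n))
  }
  pairs <- which(lower.tri(diag(p)), arr.ind = TRUE)
  # lower.tri vectorization order: same as .vech_off (column-major)
  IF <- matrix(0, n, nrow(pairs))
  h <- 1e-4
  ht <- 1e-4
  for (r in seq_len(nrow(pairs))) {
    j <- labels[pairs[r, 2]]; k <- labels[pairs[r, 1]]  # col, row
    x <- get_var(j); y <- get_var(k)
    tp <- mm$type[j, k]
    rho <- mm$R[j, k]
    if (tp == "pearson") {
      z1 <- as.numeric(scale(x)); z2 <- as.numeric(scale(y))
      IF[, r] <- z1 * z2 - (rho / 2) * (z1^2 + z2^2)
    } else if (tp == "polychoric") {
      tau_x <- mm$thresholds[[j]]; tau_y <- mm$thresholds[[k]]
      score_cells <- function(tx, ty) {
        (log(.cell_probs(tx, ty, rho + h)) -
           log(.cell_probs(tx, ty, rho - h))) / (2 * h)
      }
      lp <- function(r_) log(.cell_probs(tau_x, tau_y, r_))
      d2 <- (lp(rho + h) - 2 * lp(rho) + lp(rho - h)) / h^2
      xi <- as.integer(factor(x)); yi <- as.integer(factor(y))
      cells <- cbind(xi, yi)
      A <- -mean(d2[cells])
      psi <- score_cells(tau_x, tau_y)[cells]
      # propagate threshold estimation of both margins
      for (side in 1:2) {
        tau_s <- if (side == 1) tau_x else tau_y
        lbl_s <- if (side == 1) j else k
        for (q in seq_along(tau_s)) {
          tp_ <- tau_s; tm_ <- tau_s
          tp_[q] <- tau_s[q] + ht; tm_[q] <- tau_s[q] - ht
          dpsi <- if (side == 1) {
            (score_cells(tp_, tau_y) - score_cells(tm_, tau_y)) / (2 * ht)
          } else {
            (score_cells(tau_x, tp_) - score_cells(tau_x, tm_)) / (2 * ht)
          }
          Bq <- mean(dpsi[cells])
          psi <- psi + Bq * tau_if[[lbl_s]][, q]
        }
      }
      IF[, r] <- psi / A
    } else { # polyserial
      ord_lbl <- if (j %in% il) j else k
      ordv <- if (j %in% il) x else y
      cont <- if (j %in% il) y else x
      z <- as.numeric(scale(cont))
      lev <- sort(unique(ordv))
      yidx <- as.integer(factor(ordv, levels = lev))
      tau <- mm$thresholds[[ord_lbl]]
      score_i <- function(t_) {
        (.polyserial_ll_i(rho + h, z, yidx, t_) -
           .polyserial_ll_i(rho - h, z, yidx, t_)) / (2 * h)
      }
      l_p <- .polyserial_ll_i(rho + h, z, yidx, tau)
      l_m <- .polyserial_ll_i(rho - h, z, yidx, tau)
      l_0 <- .polyserial_ll_i(rho, z, yidx, tau)
      psi <- (l_p - l_m) / (2 * h)
      A <- -mean((l_p - 2 * l_0 + l_m) / h^2)
      psi0_mean <- mean(psi)
      for (q in seq_along(tau)) {
        tp_ <- tau
        tp_[q] <- tau[q] + ht
        Bq <- (mean(score_i(tp_)) - psi0_mean) / ht  # forward difference
        psi <- psi + Bq * tau_if[[ord_lbl]][, q]
      }
      IF[, r] <- psi / A
    }
  }
  crossprod(IF) / n^2
}

# Per-observation polyserial conditional log-likelihood.
.polyserial_ll_i <- function(rho, z, yidx, tau) {
  s <- sqrt(1 - rho^2)
  K <- length(tau) + 1L
  n <- length(z)
  hi <- rep(1, n); lo <- rep(0, n)
  top <- yidx == K; bot <- yidx == 1L
  if (any(!top)) hi[!top] <- pnorm((tau[yidx[!top]] - rho * z[!top]) / s)
  if (any(!bot)) lo[!bot] <- pnorm((tau[yidx[!bot] - 1L] - rho * z[!bot]) / s)
  log(pmax(hi - lo, 1e-300))
}

.bootstrap_replicates <- function(mm, spec, estimator, B, seed, start) {
  if (B < 50) .stop_config("bootstrap needs B >= 50")
  n <- mm$n
  set.seed(.derive_seed(seed, "bootstrap"))
  idx_mat <- matrix(sample.int(n, n * B, replace = TRUE), n, B)
  reps <- matrix(NA_real_, B, length(spec$par_names),
                 dimnames = list(NULL, spec$par_names))
  failures <- 0L
  items_df <- tibble::as_tibble(as.data.frame(mm$items))
  for (b in seq_len(B)) {
    idx <- idx_mat[, b]
    rep_fit <- tryCatch({
      mmb <- mixed_matrix(items_df[idx, , drop = FALSE],
                          if (!is.null(mm$scores))
                            as.data.frame(mm$scores[idx, , drop = FALSE]),
                          policy = "listwise")
      fit_trio_sem(mmb, spec, estimator = estimator, se = "none",
                   start = start)
    }, error = function(e) NULL)
    if (is.null(rep_fit) || rep_fit$convergence$code != 0) {
      failures <- failures + 1L
    } else {
      reps[b, ] <- rep_fit$estimates
    }
  }
  if (failures > 0.1 * B) {
    abort(sprintf("bootstrap unstable: %d of %d replicates failed", failures, B),
          class = c("trionurture_instability_error", "trionurture_error"))
  }
  list(replicates = reps[stats::complete.cases(reps), , drop = FALSE],
       failures = failures)
}

#' Fit indices for a trio SEM fit
#'
#' Computes the nominal WLS test statistic `T = (n - 1) * F_min` and the
#' usual incremental and absolute indices against the independence baseline
#' (all correlations zero, thresholds free): CFI, TLI, RMSEA and SRMR.
#'
#' @param fit A `trio_sem_fit`.
#' @return Named list with `T_stat`, `df`, `cfi`, `tli`, `rmsea`, `srmr`.
#' @export
fit_indices <- function(fit) {
  stopifnot(inherits(fit, "trio_sem_fit"))
  n <- fit$n
  w <- fit$weights_w
  s <- fit$s_obs
  imp <- fit$spec$implied(.order_theta(fit$spec, fit$estimates))
  resid <- s - .vech_off(imp$R)
  F_min <- fit$F_min
  F_b <- sum(w * s^2)
  df <- fit$df
  df_b <- length(s)
  T_stat <- (n - 1) * F_min
  T_b <- (n - 1) * F_b
  cfi <- 1 - max(T_stat - df, 0) / max(T_b - df_b, T_stat - df, 0)
  if (!is.finite(cfi)) cfi <- 1
  tli <- if (df > 0 && df_b > 0 && (T_b / df_b - 1) > 0) {
    (T_b / df_b - T_stat / df) / (T_b / df_b - 1)
  } else NA_real_
  rmsea <- if (df > 0) sqrt(max(T_stat - df, 0) / (df * (n - 1))) else NA_real_
  srmr <- sqrt(mean(resid^2))
  list(T_stat = T_stat, df = df, cfi = min(cfi, 1),
       tli = if (is.finite(tli %||% NA)) min(tli, 1) else NA_real_,
       rmsea = rmsea, srmr = srmr)
}

#' @export
print.trio_sem_fit <- function(x, ...) {
  cat(sprintf("<trio_sem_fit> variant = %s, n = %d, F_min = %.3g, df = %d\n",
              x$spec$variant, x$n, x$F_min, x$df))
  cat(sprintf("  CFI = %.3f, TLI = %.3f, RMSEA = %.3f, SRMR = %.3f\n",
              x$indices$cfi, x$indices$tli %||% NA, x$indices$rmsea %||% NA,
              x$indices$srmr))
  est <- x$estimates[!startsWith(names(x$estimates), "lambda_")]
  print(round(est, 4))
  invisible(x)
}

#' @rdname fit_trio_sem
#' @param x A `trio_sem_fit`.
#' @param ... Unused.
#' @export
tidy.trio_sem_fit <- function(x, ...) {
  out <- tibble(
    term = names(x$estimates),
    estimate = unname(x$estimates),
    std.error = if (!is.null(x$se)) unname(x$se[names(x$estimates)]) else NA_real_
  )
  out <- dplyr::mutate(out,
                       statistic = .data$estimate / .data$std.error,
                       p.value = 2 * pnorm(-abs(.data$statistic)))
  if (!is.null(x$ci)) {
    out$conf.low <- x$ci[names(x$estimates), 1]
    out$conf.high <- x$ci[names(x$estimates), 2]
  } else if (!is.null(x$se)) {
    out$conf.low <- out$estimate - 1.96 * out$std.error
    out$conf.high <- out$estimate + 1.96 * out$std.error
  }
  out
}

#' @rdname fit_trio_sem
#' @export
glance.trio_sem_fit <- function(x, ...) {
  tibble(
    n = x$n, F_min = x$F_min, T_stat = x$indices$T_stat, df = x$df,
    cfi = x$indices$cfi, tli = x$indices$tli %||% NA_real_,
    rmsea = x$indices$rmsea %||% NA_real_, srmr = x$indices$srmr,
    estimator = x$estimator, converged = x$convergence$code == 0
  )
}
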
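#' Recode / collapse ordinal item categories
#'
#' Applies an order-preserving category mapping to every item column (for
#' example collapsing a 6-point response scale's options 4-6 into one
#' category, yielding a 4-point scale). Missing values are preserved.
#'
#' @param items Tibble with an id column (`child_id`, passed through) and
#'   integer item columns.
#' @param mapping Named mapping from observed to recoded categories, e.g.
#'   `c("1" = 1, "2" = 2, "3" = 3, "4" = 4, "5" = 4, "6" = 4)`, or an
#'   unnamed vector indexed by category.
#' @return Recoded tibble of the same shape.
#' @export
recode_collapse <- function(items, mapping) {
  items <- tibble::as_tibble(items)
  m <- as.integer(mapping)
  dom <- if (is.null(names(mapping))) seq_along(m) else as.integer(names(mapping))
  ord <- order(dom)
  if (is.unsorted(m[ord])) {
    abort("category mapping must be monotone non-decreasing",
          class = c("trionurture_mapping_error", "trionurture_error"))
  }
  lut <- setNames(m, dom)
  item_cols <- setdiff(names(items), "child_id")
  for (col in item_cols) {
    x <- items[[col]]
    obs <- x[!is.na(x)]
    outside <- setdiff(unique(obs), dom)
    if (length(outside)) {
      abort(sprintf("item `%s` has values outside the mapping domain: %s",
                    col, paste(outside, collapse = ", ")),
            class = c("trionurture_mapping_error", "trionurture_error"))
    }
    items[[col]] <- unname(lut[as.character(x)])
  }
  items
}

#' Cumulative-probit thresholds of an ordinal item
#'
#' The threshold below category `k` is the standard-normal quantile of the
#' complete-case cumulative proportion at or below `k`. This is stage one of
#' the ordinal measurement model: margins alone determine the thresholds.
#'
#' @param x Integer item vector (categories `1..K`, `NA` allowed).
#' @param levels Optional vector of the categories in order (defaults to the
#'   observed sorted unique values).
#' @return Numeric vector of `K - 1` strictly increasing cutpoints.
#' @export
#' @examples
#' estimate_thresholds(rep(1:4, c(50, 30, 15, 5)))  # 0, 0.8416, 1.6449
estimate_thresholds <- function(x, levels = NULL) {
  x <- x[!is.na(x)]
  if (is.null(levels)) levels <- sort(unique(x))
  if (length(levels) < 2L) {
    abort("item has fewer than 2 observed categories; collapse or drop it",
          class = c("trionurture_degenerate_error", "trionurture_error"))
  }
  counts <- as.numeric(table(factor(x, levels = levels)))
  if (any(counts == 0)) {
    abort("a declared category has zero observations; collapse categories",
          class = c("trionurture_degenerate_error", "trionurture_error"))
  }
  cum <- cumsum(counts) / sum(counts)
  qnorm(cum[-length(cum)])
}

# Rectangle probabilities of a bivariate normal over the threshold grid.
.cell_probs <- function(tau_r, tau_c, rho) {
  tr <- c(-Inf, tau_r, Inf); tc <- c(-Inf, tau_c, Inf)
  grid <- pbvnorm(rep(tr, times = length(tc)), rep(tc, each = length(tr)), rho)
  Fm <- matrix(grid, nrow = length(tr))
  P <- Fm[-1, -1, drop = FALSE] - Fm[-nrow(Fm), -1, drop = FALSE] -
    Fm[-1, -ncol(Fm), drop = FALSE] + Fm[-nrow(Fm), -ncol(Fm), drop = FALSE]
  pmax(P, 1e-12)
}

.polychoric_loglik <- function(rho, tab, tau_r, tau_c) {
  sum(tab * log(.cell_probs(tau_r, tau_c, rho)))
}

# Core polychoric estimation from a contingency table with fixed thresholds.
.polychoric_core <- function(tab, tau_r, tau_c, tol = 1e-6) {
  opt <- optimize(.polychoric_loglik, c(-0.999, 0.999), tab = tab,
                  tau_r = tau_r, tau_c = tau_c, maximum = TRUE, tol = tol)
  opt$maximum
}

#' Polychoric correlation (two-step maximum likelihood)
#'
#' Estimates the latent bivariate-normal correlation underlying two ordinal
#' variables. Thresholds are fixed at their marginal cumulative-probit
#' estimates (stage one); the correlation then maximizes the multinomial
#' likelihood of the cross-tabulation, with cell probabilities given by
#' bivariate-normal rectangle probabilities. The standard error comes from
#' the numerical curvature of the profile log-likelihood.
#'
#' @param x,y Integer ordinal vectors (pairwise-complete cases are used).
#' @return List: `rho`, `se`, `n`, `tau_x`, `tau_y`.
#' @export
polychoric <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  tab <- table(x, y)
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    abort("polychoric needs at least 2 observed categories on each variable",
          class = c("trionurture_degenerate_error", "trionurture_error"))
  }
  tau_x <- estimate_thresholds(x)
  tau_y <- estimate_thresholds(y)
  rho <- .polychoric_core(tab, tau_x, tau_y)
  h <- 1e-4
  ll <- function(r) .polychoric_loglik(r, tab, tau_x, tau_y)
  curv <- (ll(rho + h) - 2 * ll(rho) + ll(rho - h)) / h^2
  se <- if (is.finite(curv) && curv < 0) sqrt(-1 / curv) else NA_real_
  list(rho = rho, se = se, n = length(x), tau_x = tau_x, tau_y = tau_y)
}

# Polyserial log-likelihood with fixed thresholds (conditional part only;
# the marginal density of z does not involve rho).
.polyserial_loglik <- function(rho, z, yf, tau) {
  s <- sqrt(1 - rho^2)
  taue <- c(-Inf, tau, Inf)
  ll <- 0
  for (k in seq_along(levels(yf))) {
    zk <- z[unclass(yf) == k]
    if (!length(zk)) next
    hi <- if (is.finite(taue[k + 1])) pnorm((taue[k + 1] - rho * zk) / s) else 1
    lo <- if (is.finite(taue[k])) pnorm((taue[k] - rho * zk) / s) else 0
    ll <- ll + sum(log(pmax(hi - lo, 1e-300)))
  }
  ll
}

#' Polyserial correlation (two-step maximum likelihood)
#'
#' Latent correlation between a continuous score and an ordinal item under
#' bivariate normality, with item thresholds fixed from the margins and the
#' score standardized in-sample. The moment-based estimator of Olsson,
#' Drasgow and Dorans seeds a bracketed likelihood maximization.
#'
#' @param score Numeric vector.
#' @param item Integer ordinal vector.
#' @return List: `rho`, `se`, `n`, `tau`.
#' @export
polyserial <- function(score, item) {
  ok <- !is.na(score) & !is.na(item)
  z <- score[ok]; y <- item[ok]
  if (sd(z) < 1e-12) {
    abort("score has zero variance", class = c("trionurture_degenerate_error",
                                               "trionurture_error"))
  }
  z <- (z - mean(z)) / sd(z)
  lev <- sort(unique(y))
  if (length(lev) < 2L) {
    abort("item has fewer than 2 observed categories",
          class = c("trionurture_degenerate_error", "trionurture_error"))
  }
  yf <- factor(y, levels = lev)
  tau <- estimate_thresholds(y, levels = lev)
  # moment-based start
  r_xy <- cor(z, as.numeric(yf))
  start <- r_xy * sd(as.numeric(yf)) * sqrt((length(z) - 1) / length(z)) /
    sum(dnorm(tau))
  start <- min(max(start, -0.95), 0.95)
  lo <- max(start - 0.2, -0.999); hi <- min(start + 0.2, 0.999)
  opt <- optimize(.polyserial_loglik, c(lo, hi), z = z, yf = yf, tau = tau,
                  maximum = TRUE, tol = 1e-6)
  rho <- opt$maximum
  if (rho < lo + 1e-4 || rho > hi - 1e-4) {
    opt <- optimize(.polyserial_loglik, c(-0.999, 0.999), z = z, yf = yf,
                    tau = tau, maximum = TRUE, tol = 1e-6)
    rho <- opt$maximum
  }
  h <- 1e-4
  ll <- function(r) .polyserial_loglik(r, z, yf, tau)
  curv <- (ll(rho + h) - 2 * ll(rho) + ll(rho - h)) / h^2
  se <- if (is.finite(curv) && curv < 0) sqrt(-1 / curv) else NA_real_
  list(rho = rho, se = se, n = length(z), tau = tau)
}

#' Mixed correlation matrix of ordinal items and continuous scores
#'
#' Stage-one statistics for the weighted-least-squares SEM: polychoric
#' correlations among items, polyserial correlations between items and
#' scores, Pearson correlations among scores, plus per-item thresholds.
#'
#' @param items Tibble/data frame with optional `child_id` column and integer
#'   item columns.
#' @param scores Tibble/data frame (or matrix) of continuous score columns,
#'   row-aligned with `items`. `NULL` for items only.
#' @param policy Missing-data policy: `"listwise"` (default; the fitted
#'   sample is the complete-case set) or `"pairwise"`.
#' @param min_n Minimum complete cases per pair.
#' @return A `mixed_cor` object: list with `R` (correlation matrix), `type`
#'   (pair-type label matrix), `n_pair`, `thresholds`, `item_labels`,
#'   `score_labels`, `n`, `policy`, and the analysed `items`/`scores`
#'   matrices (complete-case set under listwise).
#' @export
mixed_matrix <- function(items, scores = NULL,
                         policy = c("listwise", "pairwise"), min_n = 20) {
  policy <- match.arg(policy)
  items <- tibble::as_tibble(items)
  im <- as.matrix(items[, setdiff(names(items), "child_id"), drop = FALSE])
  storage.mode(im) <- "integer"
  sm <- NULL
  if (!is.null(scores)) {
    scores <- tibble::as_tibble(as.data.frame(scores))
    keep <- names(scores)[vapply(scores, is.numeric, TRUE)]
    sm <- as.matrix(scores[, keep, drop = FALSE])
    if (nrow(sm) != nrow(im)) .stop_config("items and scores are not row-aligned")
  }
  if (policy == "listwise") {
    cc <- complete.cases(im) & (if (is.null(sm)) TRUE else complete.cases(sm))
    im <- im[cc, , drop = FALSE]
    if (!is.null(sm)) sm <- sm[cc, , drop = FALSE]
  }
  il <- colnames(im); sl <- colnames(sm)
  labels <- c(il, sl)
  p <- length(labels)
  R <- diag(1, p); dimnames(R) <- list(labels, labels)
  type <- matrix("", p, p, dimnames = dimnames(R))
  n_pair <- matrix(NA_integer_, p, p, dimnames = dimnames(R))
  get_var <- function(j) if (j <= length(il)) im[, j] else sm[, j - length(il)]
  is_item <- seq_len(p) <= length(il)
  for (j in seq_len(p - 1)) {
    for (k in (j + 1):p) {
      x <- get_var(j); y <- get_var(k)
      ok <- !is.na(x) & !is.na(y)
      if (sum(ok) < min_n) {
        abort(sprintf("pair %s-%s has only %d complete cases (minimum %d)",
                      labels[j], labels[k], sum(ok), min_n),
              class = c("trionurture_sparse_error", "trionurture_error"))
      }
      if (is_item[j] && is_item[k]) {
        est <- polychoric(x, y); tp <- "polychoric"
      } else if (!is_item[j] && !is_item[k]) {
        est <- list(rho = cor(x[ok], y[ok]), n = sum(ok)); tp <- "pearson"
      } else {
        cont <- if (is_item[j]) y else x
        ordv <- if (is_item[j]) x else y
        est <- polyserial(cont, ordv); tp <- "polyserial"
      }
      R[j, k] <- R[k, j] <- est$rho
      type[j, k] <- type[k, j] <- tp
      n_pair[j, k] <- n_pair[k, j] <- est$n
    }
  }
  thresholds <- lapply(seq_along(il), function(j) estimate_thresholds(im[, j]))
  names(thresholds) <- il
  fingerprint <- c(n = nrow(im),
                   items = sum(as.numeric(im), na.rm = TRUE),
                   scores = if (is.null(sm)) 0 else round(sum(sm^2), 6))
  structure(list(R = R, type = type, n_pair = n_pair, thresholds = thresholds,
                 item_labels = il, score_labels = sl %||% character(0),
                 n = nrow(im), policy = policy, items = im, scores = sm,
                 fingerprint = fingerprint),
            class = "mixed_cor")
}

#' @export
print.mixed_cor <- function(x, ...) {
  cat(sprintf("<mixed_cor> %d items, %d scores, n = %d (%s)\n",
              length(x$item_labels), length(x$score_labels), x$n, x$policy))
  print(round(x$R, 3))
  invisible(x)
}

#' Ordinal reliability (standardized alpha on the polychoric matrix)
#'
#' `alpha = k/(k-1) * (1 - k / sum(R))` applied to the items' polychoric
#' correlation matrix — the correlation-based (standardized) form of
#' coefficient alpha, appropriate for ordinal indicators.
#'
#' @param R A `mixed_cor` object or an item correlation matrix.
#' @return Scalar alpha.
#' @export
#' @examples
#' R <- matrix(0.5, 8, 8); diag(R) <- 1
#' ordinal_alpha(R)  # 0.8889
ordinal_alpha <- function(R) {
  if (inherits(R, "mixed_cor")) {
    R <- R$R[R$item_labels, R$item_labels, drop = FALSE]
  }
  k <- nrow(R)
  tot <- sum(R)
  if (!is.finite(tot) || tot <= 0) {
    abort("total of the correlation matrix is non-positive; alpha undefined",
          class = c("trionurture_degenerate_error", "trionurture_error"))
  }
  (k / (k - 1)) * (1 - k / tot)
}
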
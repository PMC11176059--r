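#' Simulation configuration for a synthetic trio cohort
#'
#' Builds and validates the parameter set for [simulate_trio_cohort()]. The
#' generative model is the one the trio analysis assumes: standardized
#' polygenic scores (PGS) for mother, father and child with parent-child
#' correlation ~0.5 under random mating; a standardized latent liability for
#' child conduct problems driven by the three scores; and eight ordinal items
#' loading on that liability.
#'
#' @param n_trios Number of mother-father-child trios.
#' @param n_variants Number of independent biallelic variants.
#' @param maf_range Length-2 vector; allele frequencies are drawn uniformly
#'   from this interval, which must lie in (0, 0.5].
#' @param beta_child Standardized direct effect of the child PGS on the
#'   liability (the direct genetic effect).
#' @param beta_mother,beta_father Standardized residual parental-PGS paths
#'   (genetic nurture effects).
#' @param loadings Eight standardized factor loadings in (0, 1).
#' @param thresholds Either a numeric vector of ordered cutpoints shared by
#'   all items, or a list of eight such vectors, on the standard-normal scale.
#'   The default `c(0, 0.8416, 1.6449)` yields four categories with marginal
#'   probabilities 0.50/0.30/0.15/0.05, a right-skewed pattern typical of
#'   conduct-problem questionnaire items.
#' @param spousal_corr Target correlation between maternal and paternal raw
#'   scores under assortative mating; 0 means random mating.
#' @param n_subpops Number of discrete subpopulations; values > 1 switch on
#'   population stratification (allele-frequency drift plus a liability
#'   offset).
#' @param fst Drift parameter of the Balding-Nichols frequency perturbation
#'   used when `n_subpops > 1`.
#' @param strat_shift Liability offset of the last subpopulation relative to
#'   the first (spread linearly across subpopulations).
#' @param missing_rate Marginal probability that an item response is missing.
#' @param missing_mechanism `"mcar"` or `"mar"`; under MAR the missingness
#'   probability is a logistic function of `mar_covariate`.
#' @param mar_covariate Name of the covariate column driving MAR missingness.
#' @param mar_slope Logistic slope on the (standardized) MAR covariate.
#' @param seed Integer seed; fully determines the cohort.
#' @return A `sim_config` list.
#' @export
#' @examples
#' cfg <- sim_config(n_trios = 200, n_variants = 50, beta_child = 0.14)
#' cohort <- simulate_trio_cohort(cfg)
sim_config <- function(n_trios = 1000,
                       n_variants = 500,
                       maf_range = c(0.05, 0.5),
                       beta_child = 0,
                       beta_mother = 0,
                       beta_father = 0,
                       loadings = rep(0.7, 8),
                       thresholds = c(0, 0.8416212, 1.6448536),
                       spousal_corr = 0,
                       n_subpops = 1,
                       fst = 0.02,
                       strat_shift = 0,
                       missing_rate = 0,
                       missing_mechanism = c("mcar", "mar"),
                       mar_covariate = "pc1",
                       mar_slope = 1,
                       seed = 1L) {
  .check_number(n_trios, "n_trios", lo = 1)
  .check_number(n_variants, "n_variants", lo = 1)
  if (length(maf_range) != 2L || any(!is.finite(maf_range)) ||
      maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2]) {
    .stop_config("`maf_range` must be an ordered pair within (0, 0.5]")
  }
  .check_number(beta_child, "beta_child", -1, 1)
  .check_number(beta_mother, "beta_mother", -1, 1)
  .check_number(beta_father, "beta_father", -1, 1)
  if (length(loadings) != 8L || any(loadings < 0 | loadings >= 1)) {
    .stop_config("`loadings` must be eight values in [0, 1)")
  }
  if (is.numeric(thresholds)) thresholds <- rep(list(thresholds), 8L)
  if (!is.list(thresholds) || length(thresholds) != 8L) {
    .stop_config("`thresholds` must be a numeric vector or a list of 8 vectors")
  }
  for (tau in thresholds) {
    if (length(tau) < 1L || any(!is.finite(tau)) || is.unsorted(tau, strictly = TRUE)) {
      .stop_config("item thresholds must be finite and strictly increasing")
    }
  }
  .check_number(spousal_corr, "spousal_corr", 0, 0.95)
  .check_number(n_subpops, "n_subpops", lo = 1)
  .check_number(fst, "fst", 0, 0.5)
  .check_number(strat_shift, "strat_shift", -2, 2)
  .check_number(missing_rate, "missing_rate", 0, 1 - 1e-9)
  missing_mechanism <- match.arg(missing_mechanism)
  structure(list(
    n_trios = as.integer(n_trios), n_variants = as.integer(n_variants),
    maf_range = maf_range, beta_child = beta_child,
    beta_mother = beta_mother, beta_father = beta_father,
    loadings = loadings, thresholds = thresholds,
    spousal_corr = spousal_corr, n_subpops = as.integer(n_subpops),
    fst = fst, strat_shift = strat_shift,
    missing_rate = missing_rate, missing_mechanism = missing_mechanism,
    mar_covariate = mar_covariate, mar_slope = mar_slope,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Draw per-subpopulation allele frequencies (Balding-Nichols drift around a
# shared ancestral frequency).
.subpop_freqs <- function(p_anc, n_subpops, fst) {
  if (n_subpops == 1L || fst == 0) {
    return(matrix(p_anc, nrow = n_subpops, ncol = length(p_anc), byrow = TRUE))
  }
  a <- p_anc * (1 - fst) / fst
  b <- (1 - p_anc) * (1 - fst) / fst
  out <- matrix(0, n_subpops, length(p_anc))
  for (s in seq_len(n_subpops)) {
    out[s, ] <- pmin(pmax(stats::rbeta(length(p_anc), a, b), 1e-4), 1 - 1e-4)
  }
  out
}

#' Simulate the parental generation with optional assortative mating
#'
#' Draws maternal and paternal genotype dosage matrices and pairs them into
#' couples. Under assortative mating, mothers sorted by raw score are matched
#' to fathers sorted by a noisy copy of their raw score, calibrated so the
#' realized spousal score correlation hits `config$spousal_corr`.
#'
#' @param config A [sim_config()].
#' @return A list with `mother`, `father` (dosage matrices, rows = couples in
#'   matched order), `weights` (per-variant effect weights used for the true
#'   score), `freqs` (ancestral allele frequencies), and `subpop` (integer
#'   subpopulation label per couple).
#' @export
simulate_parents <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  n <- config$n_trios; v <- config$n_variants
  p_anc <- runif(v, config$maf_range[1], config$maf_range[2])
  pf <- .subpop_freqs(p_anc, config$n_subpops, config$fst)
  subpop <- rep_len(seq_len(config$n_subpops), n)
  weights <- rnorm(v)

  draw <- function() {
    g <- matrix(0L, n, v)
    for (s in seq_len(config$n_subpops)) {
      idx <- which(subpop == s)
      g[idx, ] <- matrix(rbinom(length(idx) * v, 2L, rep(pf[s, ], each = length(idx))),
                         nrow = length(idx))
    }
    g
  }
  gm <- draw(); gf <- draw()

  if (config$spousal_corr > 0) {
    # mate within subpopulation by score rank; the noisy father key has
    # correlation spousal_corr with his true score, so comonotone matching
    # transfers that correlation to the couple.
    rho <- config$spousal_corr
    sm <- as.numeric(gm %*% weights)
    sf <- as.numeric(gf %*% weights)
    zf <- (sf - mean(sf)) / sd(sf)
    key <- rho * zf + sqrt(1 - rho^2) * rnorm(n)
    ord_f <- integer(n)
    for (s in seq_len(config$n_subpops)) {
      idx <- which(subpop == s)
      ord_f[idx[order(sm[idx])]] <- idx[order(key[idx])]
    }
    gf <- gf[ord_f, , drop = FALSE]
  }
  list(mother = gm, father = gf, weights = weights, freqs = p_anc, subpop = subpop)
}

#' Mendelian transmission of parental genotypes
#'
#' For each locus the child receives one allele from each parent: a
#' homozygous parent transmits its allele deterministically and a
#' heterozygote transmits the alternative allele with probability 0.5.
#'
#' @param mother,father Dosage matrices in \{0, 1, 2\} of identical dimension,
#'   rows = couples.
#' @return Child dosage matrix of the same dimension.
#' @export
mendelian_transmit <- function(mother, father) {
  if (!all(dim(mother) == dim(father))) {
    abort("maternal and paternal genotype matrices must have identical dimensions",
          class = c("trionurture_shape_error", "trionurture_error"))
  }
  nv <- length(mother)
  m_allele <- rbinom(nv, 1L, as.numeric(mother) / 2)
  f_allele <- rbinom(nv, 1L, as.numeric(father) / 2)
  matrix(m_allele + f_allele, nrow = nrow(mother), ncol = ncol(mother))
}

#' Latent liability from trio polygenic scores
#'
#' Builds the standardized conduct-problems liability
#' `beta_C * PGS_C + beta_M * PGS_M + beta_F * PGS_F + offset + residual`,
#' with the residual variance chosen so the marginal liability variance is 1.
#'
#' @param child_pgs,mother_pgs,father_pgs Standardized score vectors.
#' @param config A [sim_config()].
#' @param offset Optional stratification offset vector (default 0).
#' @return Numeric liability vector.
#' @export
simulate_liability <- function(child_pgs, mother_pgs, father_pgs, config,
                               offset = 0) {
  systematic <- config$beta_child * child_pgs +
    config$beta_mother * mother_pgs +
    config$beta_father * father_pgs + offset
  v_sys <- var(systematic)
  if (length(systematic) < 2 || !is.finite(v_sys)) v_sys <- 0
  v_res <- 1 - v_sys
  if (v_res < 0) {
    .stop_config("structural paths imply negative residual liability variance")
  }
  as.numeric(systematic + rnorm(length(child_pgs), 0, sqrt(v_res)))
}

#' Ordinal items from a latent liability
#'
#' Each item's latent response is `lambda_j * liability` plus an independent
#' unique factor scaled to unit total variance; the observed category is one
#' plus the number of thresholds below the latent response.
#'
#' @param liability Standardized liability vector.
#' @param loadings Eight loadings in \[0, 1).
#' @param thresholds List of eight strictly increasing cutpoint vectors (or a
#'   single shared numeric vector).
#' @return Integer matrix `n x 8` of categories `1..K`.
#' @export
liability_to_items <- function(liability, loadings, thresholds) {
  if (is.numeric(thresholds)) thresholds <- rep(list(thresholds), length(loadings))
  stopifnot(length(loadings) == length(thresholds))
  for (tau in thresholds) {
    if (is.unsorted(tau, strictly = TRUE)) {
      .stop_config("item thresholds must be strictly increasing")
    }
  }
  n <- length(liability)
  out <- matrix(0L, n, length(loadings))
  for (j in seq_along(loadings)) {
    lam <- loadings[j]
    ystar <- lam * liability + sqrt(1 - lam^2) * rnorm(n)
    out[, j] <- 1L + findInterval(ystar, thresholds[[j]])
  }
  colnames(out) <- paste0("item", seq_along(loadings))
  out
}

#' Inject item missingness
#'
#' Blanks item responses either completely at random (MCAR) or at random
#' conditional on a covariate (MAR, logistic in the covariate with the
#' intercept solved so the marginal missing rate matches `config$missing_rate`).
#'
#' @param items Integer item matrix.
#' @param covariates Tibble of child covariates (only used under MAR).
#' @param config A [sim_config()].
#' @return Item matrix with `NA`s inserted.
#' @export
apply_missingness <- function(items, covariates, config) {
  rate <- config$missing_rate
  if (rate == 0) return(items)
  n <- nrow(items); k <- ncol(items)
  if (config$missing_mechanism == "mcar") {
    miss <- matrix(runif(n * k) < rate, n, k)
  } else {
    x <- covariates[[config$mar_covariate]]
    if (is.null(x)) {
      .stop_config(sprintf("MAR covariate `%s` not found", config$mar_covariate))
    }
    x <- as.numeric(scale(x))
    b <- config$mar_slope
    a <- stats::uniroot(function(a) mean(stats::plogis(a + b * x)) - rate,
                        c(-30, 30))$root
    p <- stats::plogis(a + b * x)
    miss <- matrix(runif(n * k) < rep(p, k), n, k)
  }
  items[miss] <- NA_integer_
  items
}

#' Simulate a complete synthetic trio cohort
#'
#' Runs the full generative chain: parental genotypes (with optional
#' assortative mating and stratification), Mendelian transmission, true
#' polygenic scores, latent liability, ordinal items, and missingness. The
#' returned object carries the ground-truth parameters for use in recovery
#' and power studies.
#'
#' @param config A [sim_config()] (or a list of its arguments).
#' @param keep_genotypes Keep the dosage matrices in the returned object
#'   (set `FALSE` to save memory in replicate studies; scores are kept).
#' @return A `trio_cohort` object: list with `family_id`, `genotypes`
#'   (list of mother/father/child dosage matrices or `NULL`), `weights`,
#'   `scores` (tibble of standardized per-role scores), `scores_raw`,
#'   `covariates`, `items` (tibble: `child_id` + 8 item columns), and
#'   `truth` (the config plus realized quantities).
#' @export
simulate_trio_cohort <- function(config, keep_genotypes = TRUE) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  set.seed(config$seed)
  n <- config$n_trios

  parents <- simulate_parents(config)
  child <- mendelian_transmit(parents$mother, parents$father)
  w <- parents$weights

  raw <- tibble(
    mother = as.numeric(parents$mother %*% w),
    father = as.numeric(parents$father %*% w),
    child  = as.numeric(child %*% w)
  )
  std <- dplyr::mutate(raw, dplyr::across(dplyr::everything(),
                                          ~ as.numeric(scale(.x))))

  subpop <- parents$subpop
  offset <- 0
  if (config$n_subpops > 1L && config$strat_shift != 0) {
    shifts <- seq(0, config$strat_shift, length.out = config$n_subpops)
    offset <- shifts[subpop] - mean(shifts[subpop])
  }
  liab <- simulate_liability(std$child, std$mother, std$father, config, offset)
  items <- liability_to_items(liab, config$loadings, config$thresholds)

  family_id <- sprintf("F%05d", seq_len(n))
  covariates <- tibble(
    child_id = paste0(family_id, "_C"),
    sex = rbinom(n, 1L, 0.5),
    birth_year = sample(2000:2009, n, replace = TRUE),
    subpop = factor(subpop),
    pc1 = as.numeric(scale(as.numeric(subpop) + rnorm(n, 0, 0.7)))
  )
  items <- apply_missingness(items, covariates, config)

  structure(list(
    family_id = family_id,
    genotypes = if (keep_genotypes) {
      list(mother = parents$mother, father = parents$father, child = child)
    },
    weights = w,
    freqs = parents$freqs,
    scores_raw = dplyr::bind_cols(tibble(family_id = family_id), raw),
    scores = dplyr::bind_cols(tibble(family_id = family_id), std),
    covariates = covariates,
    items = dplyr::bind_cols(tibble(child_id = covariates$child_id),
                             tibble::as_tibble(items)),
    liability = liab,
    truth = unclass(config)
  ), class = "trio_cohort")
}

#' @export
print.trio_cohort <- function(x, ...) {
  cat(sprintf("<trio_cohort> %d trios, %d variants\n",
              length(x$family_id), length(x$weights)))
  cat(sprintf("  true paths: beta_C = %.3g, beta_M = %.3g, beta_F = %.3g\n",
              x$truth$beta_child, x$truth$beta_mother, x$truth$beta_father))
  cat(sprintf("  spousal_corr = %.2f, subpops = %d, missing_rate = %.2f (%s)\n",
              x$truth$spousal_corr, x$truth$n_subpops,
              x$truth$missing_rate, x$truth$missing_mechanism))
  invisible(x)
}

#' Write a trio cohort to plain-text files
#'
#' Writes one dosage matrix per role (TSV or PLINK `.raw` dialect), a trio
#' index TSV, items CSV, covariates CSV, and a ground-truth JSON.
#'
#' @param cohort A `trio_cohort`.
#' @param dir Output directory (created if needed).
#' @param format `"tsv"` (variant-ID header, one row per individual) or
#'   `"raw"` (PLINK .raw dialect with `IID` and `<variant>_<allele>` headers).
#' @return Invisibly, the named vector of files written.
#' @export
write_cohort <- function(cohort, dir, format = c("tsv", "raw")) {
  format <- match.arg(format)
  stopifnot(inherits(cohort, "trio_cohort"))
  if (is.null(cohort$genotypes)) {
    abort("cohort was simulated with keep_genotypes = FALSE; nothing to write",
          class = "trionurture_error")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vid <- sprintf("rs%05d", seq_along(cohort$weights))
  files <- c()
  for (role in c("mother", "father", "child")) {
    g <- cohort$genotypes[[role]]
    iid <- paste0(cohort$family_id, "_", toupper(substr(role, 1, 1)))
    path <- file.path(dir, paste0("dosage_", role,
                                  if (format == "raw") ".raw" else ".tsv"))
    if (format == "raw") {
      hdr <- c("FID", "IID", paste0(vid, "_A"))
      df <- data.frame(FID = cohort$family_id, IID = iid, g, check.names = FALSE)
    } else {
      hdr <- c("IID", vid)
      df <- data.frame(IID = iid, g, check.names = FALSE)
    }
    colnames(df) <- hdr
    readr::write_tsv(df, path)
    files[paste0("dosage_", role)] <- path
  }
  idx <- tibble(family_id = cohort$family_id,
                child_id = paste0(cohort$family_id, "_C"),
                mother_id = paste0(cohort$family_id, "_M"),
                father_id = paste0(cohort$family_id, "_F"))
  readr::write_tsv(idx, file.path(dir, "trios.tsv"))
  readr::write_csv(cohort$items, file.path(dir, "items.csv"))
  readr::write_csv(cohort$covariates, file.path(dir, "covariates.csv"))
  wt <- tibble(variant_id = vid, chr = 1L, pos = seq_along(vid),
               effect_allele = "A", other_allele = "G",
               beta = cohort$weights, maf = cohort$freqs, info = 1)
  readr::write_tsv(wt, file.path(dir, "weights.tsv"))
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  files[c("trios", "items", "covariates", "weights", "truth")] <-
    file.path(dir, c("trios.tsv", "items.csv", "covariates.csv",
                     "weights.tsv", "truth.json"))
  invisible(files)
}
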
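#' GWAS inclusion filter on SNP-heritability
#'
#' A discovery GWAS qualifies for polygenic scoring when its SNP-based
#' heritability exceeds 5\% and the heritability Z-score (h2 / SE) exceeds 2.
#'
#' @param meta A data frame with columns `trait`, `h2_snp`, `h2_se` (one row
#'   per candidate GWAS), or a single-row list with those fields.
#' @return A tibble with the input columns plus `z` and logical `included`.
#' @export
#' @examples
#' gwas_inclusion_filter(data.frame(trait = "adhd", h2_snp = 0.22, h2_se = 0.01))
gwas_inclusion_filter <- function(meta) {
  meta <- tibble::as_tibble(meta)
  stopifnot(all(c("h2_snp", "h2_se") %in% names(meta)))
  if (any(!is.finite(meta$h2_se) | meta$h2_se <= 0)) {
    abort("`h2_se` must be positive", class = c("trionurture_meta_error",
                                                "trionurture_error"))
  }
  if (any(meta$h2_snp < 0 | meta$h2_snp > 1)) {
    abort("`h2_snp` must lie in [0, 1]", class = c("trionurture_meta_error",
                                                   "trionurture_error"))
  }
  dplyr::mutate(meta,
                z = .data$h2_snp / .data$h2_se,
                included = .data$h2_snp > 0.05 & .data$z > 2)
}

#' QC-filter per-variant score weights
#'
#' Applies the standard summary-statistic filters: autosomal chromosomes
#' only, MAF > 0.01, INFO > 0.8 (where an INFO column is available),
#' strand-ambiguous allele pairs (A/T, T/A, C/G, G/C) removed, and duplicated
#' variant IDs removed entirely. The retained set is independent of input row
#' order.
#'
#' @param weights Data frame with columns `variant_id`, `chr`, `effect_allele`,
#'   `other_allele`, `beta`, `maf`, and optionally `info`.
#' @param maf_min,info_min Filter cutoffs.
#' @return A list with `weights` (retained tibble) and `log` (named counts of
#'   exclusions per rule: maf, info, ambiguous, duplicate, nonautosomal).
#' @export
qc_summary_stats <- function(weights, maf_min = 0.01, info_min = 0.8) {
  w <- tibble::as_tibble(weights)
  need <- c("variant_id", "chr", "effect_allele", "other_allele", "beta", "maf")
  missing_cols <- setdiff(need, names(w))
  if (length(missing_cols)) {
    abort(paste0("weights table lacks columns: ",
                 paste(missing_cols, collapse = ", ")),
          class = c("trionurture_parse_error", "trionurture_error"))
  }
  bad <- !(w$effect_allele %in% c("A", "C", "G", "T")) |
    !(w$other_allele %in% c("A", "C", "G", "T"))
  if (any(bad)) {
    abort(sprintf("malformed allele codes in rows: %s",
                  paste(utils::head(which(bad), 5), collapse = ", ")),
          class = c("trionurture_parse_error", "trionurture_error"))
  }
  chr <- toupper(sub("^chr", "", as.character(w$chr), ignore.case = TRUE))
  autosomal <- chr %in% as.character(1:22)
  pair <- paste0(w$effect_allele, "/", w$other_allele)
  ambiguous <- pair %in% c("A/T", "T/A", "C/G", "G/C")
  dup_ids <- unique(w$variant_id[duplicated(w$variant_id)])
  duplicate <- w$variant_id %in% dup_ids
  maf_fail <- !(w$maf > maf_min)
  info_fail <- if ("info" %in% names(w)) {
    !is.na(w$info) & !(w$info > info_min)
  } else rep(FALSE, nrow(w))

  keep <- autosomal & !ambiguous & !duplicate & !maf_fail & !info_fail
  log <- c(nonautosomal = sum(!autosomal), maf = sum(maf_fail),
           info = sum(info_fail), ambiguous = sum(ambiguous),
           duplicate = sum(duplicate))
  list(weights = w[keep, , drop = FALSE], log = as.list(log))
}

#' Compute raw polygenic scores
#'
#' Weighted allele sums: `score_i = sum_v dosage_iv * weight_v`, after
#' matching dosage columns to weights by variant ID and aligning the counted
#' allele (a dosage counted on the other allele is flipped, `d -> 2 - d`).
#' Variants absent from the genotypes, or with allele pairs matching neither
#' exactly nor as a swap, are skipped and logged.
#'
#' @param genotypes Numeric dosage matrix (rows = individuals) with variant
#'   IDs as column names, or column names in the PLINK `.raw` dialect
#'   `<variant>_<counted allele>`.
#' @param weights QC'd weights tibble (see [qc_summary_stats()]).
#' @return A list with `score` (numeric vector), `n_used`, and `skipped`
#'   (tibble of variant_id + reason).
#' @export
compute_pgs <- function(genotypes, weights) {
  w <- tibble::as_tibble(weights)
  g <- as.matrix(genotypes)
  cn <- colnames(g)
  if (is.null(cn)) {
    abort("genotype matrix must carry variant IDs as column names",
          class = c("trionurture_parse_error", "trionurture_error"))
  }
  # PLINK .raw dialect: strip the trailing _<allele>, remember the counted allele
  raw_dialect <- grepl("_[ACGT]$", cn)
  counted <- ifelse(raw_dialect, sub("^.*_([ACGT])$", "\\1", cn), NA_character_)
  vid <- ifelse(raw_dialect, sub("_[ACGT]$", "", cn), cn)

  idx <- match(w$variant_id, vid)
  present <- !is.na(idx)
  flip <- rep(FALSE, nrow(w))
  mismatched <- rep(FALSE, nrow(w))
  has_allele <- present & !is.na(counted[idx])
  ca <- counted[idx]
  flip[has_allele] <- ca[has_allele] == w$other_allele[has_allele]
  mismatched[has_allele] <- !(ca[has_allele] %in% c(w$effect_allele[has_allele],
                                                    w$other_allele[has_allele]))
  use <- present & !mismatched
  if (!any(use)) {
    abort("no overlapping variants between weights and genotypes",
          class = c("trionurture_overlap_error", "trionurture_error"))
  }
  dos <- g[, idx[use], drop = FALSE]
  if (any(flip[use])) {
    dos[, flip[use]] <- 2 - dos[, flip[use], drop = FALSE]
  }
  score <- as.numeric(dos %*% w$beta[use])
  skipped <- dplyr::bind_rows(
    tibble(variant_id = w$variant_id[!present], reason = "absent"),
    tibble(variant_id = w$variant_id[mismatched & present], reason = "allele_mismatch")
  )
  list(score = score, n_used = sum(use), skipped = skipped)
}

#' Residualize scores on covariates and standardize
#'
#' Regresses each score column on the covariates by least squares (categorical
#' covariates expanded to indicator contrasts) and returns the z-scored
#' residuals — the standardization used before model fitting, so that each
#' analysed score has mean 0, variance 1, and zero sample correlation with
#' every covariate.
#'
#' @param scores Data frame: id columns (any non-numeric or columns named in
#'   `id_cols`) plus numeric score columns.
#' @param covariates Data frame of covariates aligned row-wise to `scores`
#'   (an intercept is always included). `NULL` means standardize only.
#' @param id_cols Character vector of columns to pass through untouched.
#' @return Tibble of the same shape with score columns replaced by
#'   standardized residuals.
#' @export
residualize_standardize <- function(scores, covariates = NULL,
                                    id_cols = intersect(c("family_id", "individual_id", "role"),
                                                        names(scores))) {
  scores <- tibble::as_tibble(scores)
  score_cols <- setdiff(names(scores)[vapply(scores, is.numeric, TRUE)], id_cols)
  if (!length(score_cols)) .stop_config("no numeric score columns found")
  if (is.null(covariates)) {
    X <- matrix(1, nrow(scores), 1)
    colnames(X) <- "(Intercept)"
  } else {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != nrow(scores)) {
      .stop_config("covariate rows do not align with score rows")
    }
    X <- stats::model.matrix(~ ., data = covariates)
  }
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    abort(sprintf("covariate matrix is rank-deficient; collinear columns: %s",
                  paste(dropped, collapse = ", ")),
          class = c("trionurture_collinearity_error", "trionurture_error"))
  }
  out <- scores
  for (sc in score_cols) {
    r <- qr.resid(qr_x, scores[[sc]])
    s <- sd(r)
    if (!is.finite(s) || s < 1e-10) {
      abort(sprintf("score `%s` has (near) zero residual variance; cannot standardize", sc),
            class = c("trionurture_degenerate_error", "trionurture_error"))
    }
    out[[sc]] <- (r - mean(r)) / s
  }
  out
}

#' Filter cross-family relatedness
#'
#' Removes whole families so that no two retained individuals in different
#' families share identity-by-descent above `threshold` (default 0.1768, the
#' boundary between first- and second-degree relatives). Within-family pairs
#' are expected to be related and are ignored. When a cross-family pair
#' exceeds the threshold, the family whose `family_id` sorts later is removed
#' — a deterministic, input-order-independent tie rule.
#'
#' @param kinship Data frame with columns `id1`, `id2`, `kinship` (IBD
#'   proportion in \[0, 1\]).
#' @param trios Trio index: data frame with `family_id`, `child_id`,
#'   `mother_id`, `father_id`.
#' @param threshold IBD-proportion cutoff; pairs strictly above it trigger
#'   removal.
#' @return List with `retained` (character family ids), `removed`, and
#'   `log` (tibble of offending pairs and the family removed for each).
#' @export
filter_relatedness <- function(kinship, trios, threshold = 0.1768) {
  kinship <- tibble::as_tibble(kinship)
  trios <- tibble::as_tibble(trios)
  fam_of <- c(setNames(trios$family_id, trios$child_id),
              setNames(trios$family_id, trios$mother_id),
              setNames(trios$family_id, trios$father_id))
  unknown <- setdiff(c(kinship$id1, kinship$id2), names(fam_of))
  if (length(unknown)) {
    abort(sprintf("kinship pairs reference unknown individuals: %s",
                  paste(utils::head(unknown, 5), collapse = ", ")),
          class = c("trionurture_reference_error", "trionurture_error"))
  }
  if (any(kinship$kinship < 0 | kinship$kinship > 1)) {
    .stop_config("kinship values must lie in [0, 1]")
  }
  f1 <- fam_of[kinship$id1]; f2 <- fam_of[kinship$id2]
  cross <- f1 != f2 & kinship$kinship > threshold
  offending <- tibble(
    family_a = pmin(f1[cross], f2[cross]),
    family_b = pmax(f1[cross], f2[cross]),
    kinship = kinship$kinship[cross]
  )
  offending <- dplyr::arrange(offending, .data$family_a, .data$family_b)
  removed <- character(0)
  log_rows <- list()
  for (i in seq_len(nrow(offending))) {
    a <- offending$family_a[i]; b <- offending$family_b[i]
    if (a %in% removed || b %in% removed) next
    drop <- max(a, b)  # later-sorting family id
    removed <- c(removed, drop)
    log_rows[[length(log_rows) + 1]] <-
      tibble(family_a = a, family_b = b, kinship = offending$kinship[i],
             removed = drop)
  }
  list(retained = setdiff(trios$family_id, removed),
       removed = removed,
       log = if (length(log_rows)) dplyr::bind_rows(log_rows) else
         tibble(family_a = character(), family_b = character(),
                kinship = numeric(), removed = character()))
}

# readers ---------------------------------------------------------------------

#' Read a per-variant weights TSV
#'
#' Expected columns: variant_id, chr, pos, effect_allele, other_allele, beta,
#' maf, and optionally info.
#' @param path File path.
#' @return Tibble of weights.
#' @export
read_weights <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Read a dosage matrix (plain TSV or PLINK .raw dialect)
#'
#' A plain TSV has an `IID` column and one column per variant ID; the `.raw`
#' dialect additionally has `FID` (and optionally PAT/MAT/SEX/PHENOTYPE)
#' columns and `<variant>_<allele>` headers, which are preserved so
#' [compute_pgs()] can align the counted allele.
#'
#' @param path File path.
#' @return List with `ids` (character) and `dosage` (numeric matrix).
#' @export
read_dosage <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  meta_cols <- intersect(c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE"),
                         names(d))
  if (!"IID" %in% names(d)) {
    abort("dosage file must contain an IID column",
          class = c("trionurture_parse_error", "trionurture_error"))
  }
  ids <- as.character(d$IID)
  g <- as.matrix(d[, setdiff(names(d), meta_cols), drop = FALSE])
  storage.mode(g) <- "numeric"
  list(ids = ids, dosage = g)
}
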
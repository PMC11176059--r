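test_that("config validation rejects impossible settings", {
  expect_error(sim_config(n_variants = 0), class = "trionurture_config_error")
  expect_error(sim_config(maf_range = c(0.6, 0.7)), class = "trionurture_config_error")
  expect_error(sim_config(maf_range = c(0.2, 0.1)), class = "trionurture_config_error")
  expect_error(sim_config(thresholds = c(1, 0.5)), class = "trionurture_config_error")
  expect_error(sim_config(loadings = rep(0.7, 5)), class = "trionurture_config_error")
  expect_error(sim_config(missing_rate = 1), class = "trionurture_config_error")
  # paths explaining more than the total liability variance
  cfg <- sim_config(n_trios = 200, n_variants = 50, beta_child = 0.9,
                    beta_mother = 0.9, beta_father = 0.9)
  expect_error(simulate_trio_cohort(cfg), class = "trionurture_config_error")
})

test_that("Mendelian transmission is consistent and deterministic at homozygotes", {
  m <- matrix(c(2L, 0L, 1L), 1000, 3, byrow = TRUE)
  f <- matrix(c(2L, 2L, 1L), 1000, 3, byrow = TRUE)
  set.seed(1)
  child <- mendelian_transmit(m, f)
  expect_true(all(child[, 1] == 2))            # 2 x 2 -> 2
  expect_true(all(child[, 2] == 1))            # 0 x 2 -> forced heterozygote
  expect_true(all(child[, 3] %in% 0:2))        # het x het -> anything
  expect_true(all(abs(child - (m + f) / 2) <= 1))
  expect_error(mendelian_transmit(m, f[1:10, ]), class = "trionurture_shape_error")
})

test_that("cohort-wide Mendelian consistency and seed determinism hold", {
  cfg <- sim_config(n_trios = 400, n_variants = 80, beta_child = 0.2, seed = 31)
  a <- simulate_trio_cohort(cfg)
  b <- simulate_trio_cohort(cfg)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$items, b$items)
  expect_identical(a$scores, b$scores)
  g <- a$genotypes
  expect_true(all(abs(g$child - (g$mother + g$father) / 2) <= 1))
  # impossible combinations never occur
  both0 <- g$mother == 0 & g$father == 0
  both2 <- g$mother == 2 & g$father == 2
  expect_true(all(g$child[both0] == 0))
  expect_true(all(g$child[both2] == 2))
  expect_true(all(a$items[, -1] >= 1 & a$items[, -1] <= 4, na.rm = TRUE))
})

test_that("random mating yields uncorrelated spouses; assortment hits its target", {
  co0 <- simulate_trio_cohort(sim_config(n_trios = 5000, n_variants = 300, seed = 11),
                              keep_genotypes = FALSE)
  expect_lt(abs(cor(co0$scores_raw$mother, co0$scores_raw$father)), 0.03)
  co3 <- simulate_trio_cohort(sim_config(n_trios = 5000, n_variants = 300,
                                         spousal_corr = 0.3, seed = 11),
                              keep_genotypes = FALSE)
  expect_lt(abs(cor(co3$scores_raw$mother, co3$scores_raw$father) - 0.3), 0.05)
})

test_that("parent-child score correlation is ~0.5 and increases with assortment", {
  r <- vapply(c(0, 0.2, 0.4), function(rs) {
    co <- simulate_trio_cohort(sim_config(n_trios = 4000, n_variants = 250,
                                          spousal_corr = rs, seed = 17),
                               keep_genotypes = FALSE)
    cor(co$scores$child, co$scores$mother)
  }, numeric(1))
  expect_lt(abs(r[1] - 0.5), 0.03)
  expect_true(all(diff(r) > 0))
})

test_that("stratification shifts subpopulation score means", {
  co <- simulate_trio_cohort(sim_config(n_trios = 3000, n_variants = 200,
                                        n_subpops = 2, fst = 0.05, seed = 23),
                             keep_genotypes = FALSE)
  mu <- tapply(co$scores_raw$child, co$covariates$subpop, mean)
  expect_gt(abs(mu[1] - mu[2]), 1e-6)
})

test_that("liability is standardized and reflects the configured paths", {
  cfg0 <- sim_config(n_trios = 20000, n_variants = 200, seed = 41)
  co0 <- simulate_trio_cohort(cfg0, keep_genotypes = FALSE)
  expect_lt(abs(var(co0$liability) - 1), 0.05)
  expect_lt(abs(cor(co0$liability, co0$scores$child)), 0.025)

  cfg1 <- sim_config(n_trios = 20000, n_variants = 200, beta_child = 0.14, seed = 43)
  co1 <- simulate_trio_cohort(cfg1, keep_genotypes = FALSE)
  expect_lt(abs(cor(co1$liability, co1$scores$child) - 0.14), 0.02)

  cfg2 <- sim_config(n_trios = 20000, n_variants = 200, beta_mother = 0.05, seed = 47)
  co2 <- simulate_trio_cohort(cfg2, keep_genotypes = FALSE)
  expect_lt(abs(cor(co2$liability, co2$scores$mother) - 0.05), 0.02)
})

test_that("items follow the threshold-implied margins", {
  set.seed(5)
  liab <- rnorm(20000)
  # zero loading: categories follow the marginal normal probabilities
  items <- liability_to_items(liab, loadings = c(0, 0.7, rep(0.5, 6)),
                              thresholds = c(0, 0.8416212, 1.6448536))
  freq <- tabulate(items[, 1], 4) / 20000
  expect_lt(max(abs(freq - c(0.5, 0.3, 0.15, 0.05))), 0.015)
  expect_lt(abs(cor(items[, 1], liab)), 0.02)
  # single threshold at 0: binary 50/50
  bin <- liability_to_items(liab, loadings = rep(0.5, 8),
                            thresholds = rep(list(0), 8))
  expect_lt(abs(mean(bin[, 1] == 1) - 0.5), 0.02)
  expect_error(liability_to_items(liab, rep(0.5, 8), c(1, 0.5)),
               class = "trionurture_config_error")
})

test_that("missingness matches its rate and mechanism", {
  cfg <- sim_config(n_trios = 10000, n_variants = 60, seed = 53)
  co <- simulate_trio_cohort(cfg, keep_genotypes = FALSE)
  items <- as.matrix(co$items[, -1])

  expect_identical(apply_missingness(items, co$covariates, cfg), items)

  cfg_mcar <- sim_config(n_trios = 10000, n_variants = 60, missing_rate = 0.5,
                         seed = 53)
  set.seed(7)
  miss <- apply_missingness(items, co$covariates, cfg_mcar)
  expect_lt(abs(mean(is.na(miss)) - 0.5), 0.02)

  cfg_mar <- sim_config(n_trios = 10000, n_variants = 60, missing_rate = 0.3,
                        missing_mechanism = "mar", mar_covariate = "pc1",
                        mar_slope = 1.5, seed = 53)
  set.seed(8)
  mar <- apply_missingness(items, co$covariates, cfg_mar)
  expect_lt(abs(mean(is.na(mar)) - 0.3), 0.02)
  # missingness rises with the driving covariate
  expect_gt(cor(rowMeans(is.na(mar)), co$covariates$pc1), 0.2)
})

test_that("cohorts round-trip through their plain-text files", {
  co <- simulate_trio_cohort(sim_config(n_trios = 40, n_variants = 12, seed = 61))
  dir <- withr::local_tempdir()
  files <- write_cohort(co, dir)
  expect_true(all(file.exists(files)))
  d <- read_dosage(files[["dosage_child"]])
  expect_equal(unname(d$dosage), unname(co$genotypes$child))
  w <- read_weights(files[["weights"]])
  expect_equal(w$beta, co$weights)
  # PLINK .raw dialect carries the counted allele in the header
  write_cohort(co, dir, format = "raw")
  draw <- read_dosage(file.path(dir, "dosage_child.raw"))
  expect_true(all(grepl("_A$", colnames(draw$dosage))))
  expect_equal(unname(draw$dosage), unname(co$genotypes$child))
})
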
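# Pipeline orchestration: simulate -> score -> measure -> fit -> decompose
# (-> power) from a single YAML config, with derived stage seeds and a
# hash-bearing run manifest.

.default_config <- function() {
  list(
    out = "trionurture_run",
    seed = 1L,
    stages = c("simulate", "score", "measure", "fit", "decompose"),
    simulate = list(n_trios = 1000, n_variants = 200, beta_child = 0.14),
    score = list(covariate_cols = character(0)),
    measure = list(policy = "listwise"),
    fit = list(estimator = "uls", se = "linearized", bootstrap = 0),
    decompose = list(transmission_family = NULL, nurture_family = NULL),
    power = NULL
  )
}

.load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      .stop_config(sprintf("config file `%s` does not exist", config))
    }
    config <- yaml::read_yaml(config)
  }
  modifyList(.default_config(), config)
}

#' Validate a pipeline configuration
#'
#' Checks parameter ranges, threshold ordering, stage names and referenced
#' file existence without running anything or mutating state.
#'
#' @param config Path to a YAML config or a config list.
#' @return Tibble with columns `field`, `ok`, `message`; the run is valid iff
#'   `all(ok)`.
#' @export
validate_config <- function(config) {
  checks <- list()
  add <- function(field, ok, message = "") {
    checks[[length(checks) + 1]] <<- tibble(field = field, ok = ok,
                                            message = message)
  }
  cfg <- tryCatch(.load_config(config), error = function(e) e)
  if (inherits(cfg, "error")) {
    add("config", FALSE, conditionMessage(cfg))
    return(dplyr::bind_rows(checks))
  }
  known <- c("simulate", "score", "measure", "fit", "decompose", "power")
  bad_stage <- setdiff(cfg$stages, known)
  add("stages", length(bad_stage) == 0,
      if (length(bad_stage)) paste("unknown stages:", paste(bad_stage, collapse = ", ")) else "")
  sim_cfg <- tryCatch(do.call(sim_config, c(cfg$simulate, list(seed = cfg$seed))),
                      error = function(e) e)
  add("simulate", !inherits(sim_cfg, "error"),
      if (inherits(sim_cfg, "error")) conditionMessage(sim_cfg) else "")
  for (f in c("weights", "genotypes", "items", "covariates")) {
    p <- cfg$score[[f]] %||% cfg$measure[[f]]
    if (!is.null(p)) {
      add(paste0("file:", f), file.exists(p),
          if (!file.exists(p)) paste("missing file:", p) else "")
    }
  }
  if (!is.null(cfg$fit$se)) {
    add("fit.se", cfg$fit$se %in% c("none", "linearized", "bootstrap"), "")
  }
  if (!is.null(cfg$power)) {
    psc <- tryCatch(do.call(power_scenario, cfg$power), error = function(e) e)
    add("power", !inherits(psc, "error"),
        if (inherits(psc, "error")) conditionMessage(psc) else "")
  }
  dplyr::bind_rows(checks)
}

.hash_files <- function(paths) {
  paths <- paths[file.exists(paths)]
  if (!length(paths)) return(character(0))
  setNames(as.character(tools::md5sum(paths)), basename(paths))
}

.stage_unchanged <- function(manifest_old, stage, inputs, outputs) {
  if (is.null(manifest_old)) return(FALSE)
  old <- manifest_old$stages[[stage]]
  if (is.null(old)) return(FALSE)
  if (!all(file.exists(outputs))) return(FALSE)
  identical(unclass(.hash_files(inputs)), unlist(old$input_hashes)) &&
    identical(unclass(.hash_files(outputs)), unlist(old$output_hashes))
}

#' Run the analysis pipeline from a config
#'
#' Executes the requested stages in dependency order with stage seeds derived
#' from the master seed, logging to stderr, and writes a run manifest
#' (config snapshot, stage seeds, content hashes of inputs and outputs,
#' package version, timestamps). Stages whose inputs and outputs are
#' hash-unchanged since the previous manifest are skipped.
#'
#' @param config Path to a YAML config or a config list (see
#'   [validate_config()]).
#' @param quiet Suppress progress messages.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  report <- validate_config(config)
  if (!all(report$ok)) {
    bad <- report[!report$ok, ]
    .stop_config(paste0("invalid config:\n",
                        paste0("  - ", bad$field, ": ", bad$message,
                               collapse = "\n")))
  }
  cfg <- .load_config(config)
  out <- cfg$out
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[trionurture] ", sprintf(...))
  manifest_path <- file.path(out, "manifest.json")
  manifest_old <- if (file.exists(manifest_path)) {
    tryCatch(jsonlite::read_json(manifest_path), error = function(e) NULL)
  }
  manifest <- list(config = cfg, version = as.character(utils::packageVersion("trionurture")),
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   stages = list())
  mark <- function(stage, seed, inputs, outputs) {
    manifest$stages[[stage]] <<- list(
      seed = seed,
      input_hashes = as.list(.hash_files(inputs)),
      output_hashes = as.list(.hash_files(outputs)),
      at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  }

  cohort <- NULL; scores <- NULL; mm <- NULL; fits <- NULL
  cohort_dir <- file.path(out, "cohort")

  if ("simulate" %in% cfg$stages) {
    seed <- .derive_seed(cfg$seed, "simulate")
    sim_cfg <- do.call(sim_config, c(cfg$simulate, list(seed = seed)))
    cohort_files <- file.path(cohort_dir,
                              c("dosage_mother.tsv", "dosage_father.tsv",
                                "dosage_child.tsv", "trios.tsv", "items.csv",
                                "covariates.csv", "weights.tsv", "truth.json"))
    if (.stage_unchanged(manifest_old, "simulate", character(0), cohort_files)) {
      say("simulate: outputs up to date, skipping write")
      cohort <- simulate_trio_cohort(sim_cfg)
    } else {
      say("simulate: %d trios, %d variants", sim_cfg$n_trios, sim_cfg$n_variants)
      cohort <- simulate_trio_cohort(sim_cfg)
      write_cohort(cohort, cohort_dir)
    }
    mark("simulate", seed, character(0), cohort_files)
  }

  if ("score" %in% cfg$stages) {
    say("score: QC + polygenic scoring + residualization")
    weights_path <- cfg$score$weights %||% file.path(cohort_dir, "weights.tsv")
    qc <- qc_summary_stats(read_weights(weights_path))
    jsonlite::write_json(qc$log, file.path(out, "qc_log.json"), auto_unbox = TRUE)
    score_tbl <- NULL
    for (role in c("child", "mother", "father")) {
      gpath <- cfg$score[[paste0("genotypes_", role)]] %||%
        file.path(cohort_dir, paste0("dosage_", role, ".tsv"))
      d <- read_dosage(gpath)
      pg <- compute_pgs(d$dosage, qc$weights)
      col <- tibble(!!role := pg$score)
      score_tbl <- if (is.null(score_tbl)) col else dplyr::bind_cols(score_tbl, col)
    }
    covs <- NULL
    if (length(cfg$score$covariate_cols)) {
      cov_path <- cfg$score$covariates %||% file.path(cohort_dir, "covariates.csv")
      cov_df <- readr::read_csv(cov_path, show_col_types = FALSE, progress = FALSE)
      covs <- cov_df[, cfg$score$covariate_cols, drop = FALSE]
    }
    scores <- residualize_standardize(score_tbl, covs)
    readr::write_tsv(scores, file.path(out, "scores.tsv"))
    mark("score", .derive_seed(cfg$seed, "score"),
         weights_path, file.path(out, "scores.tsv"))
  }

  if ("measure" %in% cfg$stages) {
    say("measure: thresholds + mixed correlation matrix")
    items <- if (!is.null(cfg$measure$items)) {
      readr::read_csv(cfg$measure$items, show_col_types = FALSE, progress = FALSE)
    } else cohort$items
    mm <- mixed_matrix(items, scores, policy = cfg$measure$policy %||% "listwise")
    readr::write_tsv(tibble::as_tibble(mm$R, rownames = "variable"),
                     file.path(out, "mixed_correlations.tsv"))
    jsonlite::write_json(
      list(n = mm$n, policy = mm$policy,
           pair_types = as.list(mm$type[lower.tri(mm$type)]),
           thresholds = mm$thresholds),
      file.path(out, "mixed_meta.json"), auto_unbox = TRUE, digits = NA)
    mark("measure", .derive_seed(cfg$seed, "measure"), character(0),
         file.path(out, c("mixed_correlations.tsv", "mixed_meta.json")))
  }

  if ("fit" %in% cfg$stages) {
    se_mode <- cfg$fit$se %||% "linearized"
    B <- cfg$fit$bootstrap %||% 0
    if (B > 0) se_mode <- "bootstrap"
    say("fit: trio + unadjusted models (%s, se = %s)",
        cfg$fit$estimator %||% "uls", se_mode)
    fit_seed <- .derive_seed(cfg$seed, "fit")
    fits <- list(pgs = list())
    for (variant in c("trio", "unadjusted_child", "unadjusted_mother",
                      "unadjusted_father")) {
      spec <- specify_trio_model(variant = variant)
      fits$pgs[[variant]] <- fit_trio_sem(
        mm, spec, estimator = cfg$fit$estimator %||% "uls",
        se = se_mode, B = max(B, 50), seed = fit_seed)
    }
    params <- dplyr::bind_rows(lapply(names(fits$pgs), function(v) {
      dplyr::mutate(tidy(fits$pgs[[v]]), model = v, .before = 1)
    }))
    readr::write_tsv(params, file.path(out, "fit_parameters.tsv"))
    jsonlite::write_json(
      lapply(fits$pgs, function(f) c(as.list(glance(f)),
                                     list(estimates = as.list(f$estimates)))),
      file.path(out, "fits.json"), auto_unbox = TRUE, digits = NA)
    mark("fit", fit_seed, file.path(out, "mixed_correlations.tsv"),
         file.path(out, c("fit_parameters.tsv", "fits.json")))
  }

  if ("decompose" %in% cfg$stages) {
    say("decompose: transmission / nurture report")
    report_tbl <- build_report(
      fits, transmission_family = cfg$decompose$transmission_family,
      nurture_family = cfg$decompose$nurture_family)
    write_report(report_tbl, file.path(out, "decomposition.tsv"))
    mark("decompose", .derive_seed(cfg$seed, "decompose"),
         file.path(out, "fit_parameters.tsv"),
         file.path(out, "decomposition.tsv"))
  }

  if ("power" %in% cfg$stages && !is.null(cfg$power)) {
    say("power: Monte-Carlo scenario")
    psc <- do.call(power_scenario,
                   modifyList(cfg$power,
                              list(seed = .derive_seed(cfg$seed, "power"))))
    pres <- run_power(psc, progress = !quiet)
    readr::write_tsv(summarize_power(list(main = pres)),
                     file.path(out, "power.tsv"))
    mark("power", psc$seed, character(0), file.path(out, "power.tsv"))
  }

  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  say("done: %s", out)
  invisible(manifest)
}
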
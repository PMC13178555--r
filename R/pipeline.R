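# Workflow entry point: YAML-configured stage runner used by the command-line
# script in inst/cli/ramanunmix.R.

pipeline_stage_names <- c("simulate", "preprocess", "augment", "unmix_nnls",
                          "unmix_mcr", "train_ae", "predict_ae", "benchmark")

known_keys <- list(
  top = c("stages", "outdir", "seed", "verbose", "simulate", "preprocess",
          "augment", "unmix_nnls", "unmix_mcr", "train_ae", "predict_ae",
          "benchmark"),
  simulate = c("spectra_per_spot", "replicates", "step", "c_bsa_grid", "c_al"),
  preprocess = c("crop_lo", "crop_hi", "spike_sd_threshold", "baseline_order",
                 "ref_peak_center", "ref_peak_halfwidth"),
  augment = c("source", "n_per_seed", "beta_sd_rule"),
  unmix_nnls = character(),
  unmix_mcr = c("n_components", "max_iter", "tol"),
  train_ae = c("w_c", "max_epochs", "batch_size", "learning_rate"),
  predict_ae = character(),
  benchmark = c("source", "n_per_seed", "seeds", "include_unaugmented",
                "spectra_per_spot", "step"))

check_config_keys <- function(cfg) {
  bad <- setdiff(names(cfg), known_keys$top)
  if (length(bad))
    stop(sprintf("unknown configuration key '%s'", bad[1]), call. = FALSE)
  for (stage in intersect(names(cfg), pipeline_stage_names)) {
    bad <- setdiff(names(cfg[[stage]]), known_keys[[stage]])
    if (length(bad))
      stop(sprintf("unknown configuration key '%s.%s'", stage, bad[1]),
           call. = FALSE)
  }
  invisible(cfg)
}

# stable content fingerprint of the configuration (polynomial rolling hash
# in double arithmetic; R's bitwise ops are limited to 32-bit signed ints)
config_hash <- function(cfg) {
  txt <- paste(deparse(cfg), collapse = "")
  h <- 5381
  for (b in utf8ToInt(txt)) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the spectral-unmixing workflow from a configuration
#'
#' Executes the requested stages in dependency order
#' (simulate -> preprocess -> augment -> unmixing/training -> benchmark),
#' writing each stage's artifacts under `outdir` together with a provenance
#' manifest (`run_manifest.json`: configuration echo and hash, seed, package
#' version, stages run). Re-running with the same configuration overwrites the
#' artifacts deterministically. Unknown configuration keys are rejected by
#' name.
#'
#' @param config path to a YAML configuration file, or an equivalent named
#'   list. Top-level keys: `stages` (subset of `simulate`, `preprocess`,
#'   `augment`, `unmix_nnls`, `unmix_mcr`, `train_ae`, `predict_ae`,
#'   `benchmark`; default all), `outdir`, `seed`, plus one optional section
#'   per stage.
#' @param outdir output directory (overrides the config value)
#' @return invisibly, a list of artifact paths per stage
#' @export
run_pipeline <- function(config = list(), outdir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  cfg <- check_config_keys(cfg %||% list())
  outdir <- outdir %||% cfg$outdir %||% "ramanunmix_run"
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stages <- cfg$stages %||% pipeline_stage_names
  bad <- setdiff(stages, pipeline_stage_names)
  if (length(bad)) stop(sprintf("unknown stage '%s'", bad[1]), call. = FALSE)
  seed <- as.integer(cfg$seed %||% 1L)
  verbose <- isTRUE(cfg$verbose %||% TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  artifacts <- list()
  pth <- function(...) file.path(outdir, ...)

  sc <- cfg$simulate %||% list()
  sim_cfg <- benchmark_sim_config(
    spectra_per_spot = sc$spectra_per_spot %||% 50L,
    step = sc$step %||% 4, rng_seed = seed,
    replicates = sc$replicates %||% 2L,
    c_bsa_grid = sc$c_bsa_grid %||% c(0.2, 0.5, 1, 1.5, 2),
    c_al = sc$c_al %||% 0.5)
  pc <- cfg$preprocess %||% list()
  pre_cfg <- preprocess_config(
    crop_lo = pc$crop_lo %||% 400, crop_hi = pc$crop_hi %||% 1800,
    spike_sd_threshold = pc$spike_sd_threshold %||% 4,
    baseline_order = pc$baseline_order %||% 4L,
    ref_peak_center = pc$ref_peak_center %||% 976,
    ref_peak_halfwidth = pc$ref_peak_halfwidth %||% 5)

  data <- NULL; clean <- NULL
  need_data <- length(intersect(stages, pipeline_stage_names)) > 0
  if (need_data) data <- simulate_dataset(sim_cfg)
  if ("simulate" %in% stages) {
    say("simulate: %d train spectra", n_spectra(data$train))
    for (nm in c("train", "test1", "test2"))
      write_spectra_table(data[[nm]], pth(paste0(nm, ".csv")))
    write_endmembers(data$references, pth("references.csv"))
    jsonlite::write_json(
      list(c_bsa_grid = sim_cfg$c_bsa_grid, c_al = sim_cfg$c_al,
           adsorption = unclass(sim_cfg$adsorption)),
      pth("truth.json"), auto_unbox = TRUE, digits = NA)
    artifacts$simulate <- pth(c("train.csv", "test1.csv", "test2.csv",
                                "references.csv", "truth.json"))
  }
  needs_clean <- any(c("preprocess", "augment", "unmix_nnls", "unmix_mcr",
                       "train_ae", "predict_ae") %in% stages)
  if (needs_clean) {
    pp <- preprocess_pipeline(data$train, pre_cfg)
    clean <- pp$set
    if ("preprocess" %in% stages) {
      say("preprocess: %d -> %d spectra", n_spectra(data$train), n_spectra(clean))
      write_spectra_table(clean, pth("clean.csv"))
      jsonlite::write_json(pp$log, pth("preprocess_log.json"),
                           auto_unbox = TRUE, digits = NA, force = TRUE)
      artifacts$preprocess <- pth(c("clean.csv", "preprocess_log.json"))
    }
  }
  if ("augment" %in% stages) {
    ac <- cfg$augment %||% list()
    set.seed(seed)
    cal <- build_calibration_set(clean, ac$source %||% "within_concentration")
    aug <- augment_training_set(clean, augmentation_config(
      cal, ac$n_per_seed %||% 15L,
      beta_sd_rule = ac$beta_sd_rule %||% "one_over_l", rng_seed = seed))
    say("augment: %d -> %d spectra", n_spectra(clean), n_spectra(aug))
    write_spectra_table(aug, pth("augmented.csv"))
    artifacts$augment <- pth("augmented.csv")
  }
  refs_cropped <- NULL
  if (any(c("unmix_nnls", "unmix_mcr", "train_ae", "predict_ae") %in% stages)) {
    keep <- data$references$wavenumber >= pre_cfg$crop_lo &
      data$references$wavenumber <= pre_cfg$crop_hi
    refs_cropped <- endmember_set(data$references$wavenumber[keep],
                                  data$references$spectra[, keep, drop = FALSE],
                                  data$references$labels)
  }
  if ("unmix_nnls" %in% stages) {
    um <- nnls_map(clean, refs_cropped, target = "BSA", reference = "AlOH3")
    tab <- cbind(clean$meta[, c("spectrum_id", "spot_id", "grid_x", "grid_y",
                                "c_bsa")],
                 as.data.frame(unclass(um$abundances)), ratio = um$ratio)
    utils::write.csv(tab, pth("nnls_ratios.csv"), row.names = FALSE)
    artifacts$unmix_nnls <- pth("nnls_ratios.csv")
  }
  mcr_fit <- NULL
  if (any(c("unmix_mcr", "predict_ae") %in% stages)) {
    mc <- cfg$unmix_mcr %||% list()
    mcr_fit <- mcr_als(clean, mcr_config(
      n_components = mc$n_components %||% 2L,
      max_iter = mc$max_iter %||% 500L, tol = mc$tol %||% 1e-8,
      rng_seed = seed))
    if ("unmix_mcr" %in% stages) {
      say("mcr: %d iterations", mcr_fit$n_iter)
      write_endmembers(mcr_fit$endmembers, pth("mcr_endmembers.csv"))
      utils::write.csv(as.data.frame(unclass(mcr_fit$abundances)),
                       pth("mcr_abundances.csv"), row.names = FALSE)
      jsonlite::write_json(list(error_history = mcr_fit$error_history,
                                converged = mcr_fit$converged),
                           pth("mcr_history.json"), auto_unbox = TRUE, digits = NA)
      artifacts$unmix_mcr <- pth(c("mcr_endmembers.csv", "mcr_abundances.csv",
                                   "mcr_history.json"))
    }
  }
  ae_fit <- NULL
  if (any(c("train_ae", "predict_ae") %in% stages)) {
    tc <- cfg$train_ae %||% list()
    set.seed(seed)
    cal <- build_calibration_set(clean, "within_concentration")
    aug <- augment_training_set(clean,
                                augmentation_config(cal, 15L, rng_seed = seed))
    spec <- ae_spec(w_c = tc$w_c %||% 40,
                    max_epochs = tc$max_epochs %||% 10L,
                    batch_size = tc$batch_size %||% 8L,
                    learning_rate = tc$learning_rate %||% 0.001,
                    rng_seed = seed)
    ae_fit <- ae_unmix(aug, spec)
    if ("train_ae" %in% stages) {
      say("train_ae: %d epochs, final loss %.5f", nrow(ae_fit$loss_history),
          utils::tail(ae_fit$loss_history$total, 1))
      write_endmembers(extract_endmembers(ae_fit, refs_cropped),
                       pth("ae_endmembers.csv"))
      utils::write.csv(ae_fit$loss_history, pth("ae_loss_history.csv"),
                       row.names = FALSE)
      artifacts$train_ae <- pth(c("ae_endmembers.csv", "ae_loss_history.csv"))
    }
  }
  if ("predict_ae" %in% stages) {
    test1 <- preprocess_pipeline(data$test1, pre_cfg)$set
    pred <- predict(ae_fit, test1)
    tab <- cbind(test1$meta[, c("spectrum_id", "spot_id", "c_bsa")],
                 as.data.frame(unclass(pred)))
    utils::write.csv(tab, pth("ae_test_predictions.csv"), row.names = FALSE)
    artifacts$predict_ae <- pth("ae_test_predictions.csv")
  }
  if ("benchmark" %in% stages) {
    bc <- cfg$benchmark %||% list()
    rep <- run_benchmark(
      sim_cfg = benchmark_sim_config(
        spectra_per_spot = bc$spectra_per_spot %||% sim_cfg$spectra_per_spot,
        step = bc$step %||% 4, rng_seed = seed),
      pre_cfg = pre_cfg,
      source = bc$source %||% "within_concentration",
      n_per_seed = bc$n_per_seed %||% 15L,
      seeds = as.integer(bc$seeds %||% c(3L, 15L, 22L, 34L, 42L)),
      include_unaugmented = isTRUE(bc$include_unaugmented %||% TRUE))
    write_benchmark_report(rep, pth("report.json"))
    artifacts$benchmark <- pth("report.json")
  }
  manifest <- list(package = "ramanunmix",
                   version = as.character(utils::packageVersion("ramanunmix")),
                   seed = seed, stages = stages,
                   config_hash = config_hash(cfg),
                   config = cfg,
                   timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, pth("run_manifest.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  invisible(artifacts)
}
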
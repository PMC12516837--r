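#' Configuration for an end-to-end pipeline run
#'
#' Bundles every knob of the generate -> QC -> calibrate -> train -> sweep ->
#' gate -> benchmark workflow.  Defaults are desk-scale: they exercise every
#' stage in minutes on one CPU.
#'
#' @param out_dir output directory for artifacts.
#' @param synthetic a `synthetic_config` for the cohort generator.
#' @param expert_sigmas training blur levels (must include 0).
#' @param sigma_grid validation sweep grid.
#' @param scenarios scenario ids to benchmark (subset of 1--12).
#' @param kind `"tile"` or `"attention"` track.
#' @param k_folds stratified CV folds (default 5); `fold` selects which
#'   fold's split the single fitted model uses.
#' @param fold fold index used for the fit (default 1).
#' @param lv_qc LV quality-control threshold applied to the generated
#'   tiles.  Synthetic tiles are generated sharp, so the default 0 keeps
#'   everything; real-tile manifests conventionally use 500.
#' @param calib_n tiles sampled for calibration.
#' @param control expert training settings.
#' @param seed master seed for the whole run.
#' @param write_tiles also write every tile as a PGM file (off by default;
#'   the manifest then records metadata only).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("sharpgate_run_"),
                            synthetic = synthetic_config(),
                            expert_sigmas = c(0, 0.5, 1, 2, 3, 4, 5, 6, 7, 8, 9),
                            sigma_grid = c(0, 0.5, 1, 1.5, 2, 2.5, 3, 3.5, 4,
                                           5, 6, 7, 8, 9, 10),
                            scenarios = 1:12,
                            kind = c("tile", "attention"),
                            k_folds = 5, fold = 1, lv_qc = 0,
                            calib_n = 500, control = list(), seed = 1L,
                            write_tiles = FALSE) {
  kind <- match.arg(kind)
  stopifnot(fold >= 1, fold <= k_folds, all(scenarios %in% 1:12))
  structure(as.list(environment()), class = "pipeline_config")
}

# content hash of the configuration (polynomial rolling hash over its
# deparsed form, out_dir excluded); embedded in artifacts for exact replay
config_hash <- function(config) {
  config$out_dir <- NULL
  bytes <- utf8ToInt(paste(deparse(config[order(names(config))]),
                           collapse = "\n"))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full pipeline
#'
#' Executes, in order: synthetic cohort generation, LV quality control,
#' stratified patient-level CV splitting, MoE fitting (expert training,
#' sigma-to-LV calibration, cross-blur sweep, gating derivation) and the
#' mixed-blur scenario benchmark.  Writes six artifacts to
#' `config$out_dir`: `config.json`, `manifest.csv`, `calibration.json`,
#' `gates.json`, `sensitivity.csv` and `scenario_report.csv`, each
#' reproducible bit-identically from the same configuration and seed.  Any
#' stage failure aborts with the stage name.
#'
#' @param config a `pipeline_config`.
#' @param verbose print one structured log line per stage.
#' @return invisibly, list with `fit` (the `moe` object), `report` (the
#'   `scenario_report`), `cohort` and `paths`.
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  log_stage <- function(stage, ...) {
    if (verbose) message(sprintf("stage=%s %s", stage,
                                 paste(sprintf("%s=%s", names(list(...)),
                                               unlist(list(...))),
                                       collapse = " ")))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  meta <- list(tool = "sharpgate",
               version = as.character(utils::packageVersion("sharpgate")),
               config_hash = hash, seed = config$seed)

  cohort <- stage("make-synthetic", generate_cohort(config$synthetic))
  log_stage("make-synthetic", patients = length(cohort$bags))

  cohort$bags <- stage("qc", lapply(cohort$bags, function(b) {
    qc_filter(b, config$lv_qc)$bag
  }))
  n_tiles <- sum(vapply(cohort$bags, function(b) length(b$tiles), integer(1)))
  log_stage("qc", threshold = config$lv_qc, tiles_kept = n_tiles)

  splits <- stage("cv-split",
                  make_cv_splits(cohort$patient_ids, cohort$labels,
                                 k = config$k_folds, seed = config$seed))
  split <- splits[[config$fold]]
  log_stage("cv-split", k = config$k_folds, fold = config$fold)

  fit <- stage("fit", moe_fit(cohort, split$train, split$validation,
                              expert_sigmas = config$expert_sigmas,
                              kind = config$kind,
                              sigma_grid = config$sigma_grid,
                              calib_n = config$calib_n,
                              control = config$control, seed = config$seed))
  log_stage("fit", experts = length(fit$experts),
            groups = nrow(fit$ranges))

  iva <- match(split$validation, cohort$patient_ids)
  report <- stage("benchmark",
                  scenario_benchmark(fit$baseline, fit$experts, fit$gating,
                                     cohort$bags[iva], cohort$labels[iva],
                                     scenarios = config$scenarios,
                                     seed = config$seed))
  log_stage("benchmark", scenarios = nrow(report))

  paths <- stage("write-artifacts", {
    od <- config$out_dir
    p <- list(config = file.path(od, "config.json"),
              manifest = file.path(od, "manifest.csv"),
              calibration = file.path(od, "calibration.json"),
              gates = file.path(od, "gates.json"),
              sensitivity = file.path(od, "sensitivity.csv"),
              scenarios = file.path(od, "scenario_report.csv"))
    cfg <- config
    cfg$control <- NULL
    cfg$out_dir <- NULL   # artifacts must not depend on where they live
    cfg$synthetic <- unclass(cfg$synthetic)
    jsonlite::write_json(c(meta, list(config = unclass(cfg))), p$config,
                         digits = NA, auto_unbox = TRUE, pretty = TRUE,
                         force = TRUE)
    if (config$write_tiles) {
      write_manifest(cohort, od)
    } else {
      man <- do.call(rbind, lapply(cohort$bags, function(b)
        data.frame(slide_id = b$slide_id, patient_id = b$patient_id,
                   label = b$label, tile_id = b$tile_ids,
                   base_sigma = b$base_sigma, stringsAsFactors = FALSE)))
      write.csv(man, p$manifest, row.names = FALSE)
    }
    jsonlite::write_json(c(meta, list(
      sigma = fit$calibration$entries$sigma,
      median_lv = fit$calibration$entries$median_lv,
      n_tiles_sampled = fit$calibration$n_tiles_sampled)),
      p$calibration, digits = NA, auto_unbox = TRUE, pretty = TRUE)
    jsonlite::write_json(c(meta, list(
      thresholds = fit$gating$thresholds,
      expert_ids = fit$gating$expert_ids,
      ranges = fit$ranges[, c("expert_id", "sigma_lo", "sigma_hi")])),
      p$gates, digits = NA, auto_unbox = TRUE, pretty = TRUE,
      dataframe = "columns")
    write.csv(data.frame(expert_id = rownames(fit$sensitivity),
                         unclass(fit$sensitivity), check.names = FALSE),
              p$sensitivity, row.names = FALSE)
    write.csv(as.data.frame(report), p$scenarios, row.names = FALSE)
    p
  })
  log_stage("write-artifacts", dir = config$out_dir)
  invisible(list(fit = fit, report = report, cohort = cohort, paths = paths))
}
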
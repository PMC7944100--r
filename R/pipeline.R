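#' Assemble a full pipeline run configuration
#'
#' A run is a pure function of its configuration: the same `run_config`
#' always produces byte-identical outputs. The default resting duration is
#' 60 s per condition (the minimum the analysis retains); longer sessions
#' (e.g. 90 s eyes-closed) are available through `cohort`.
#'
#' @param cohort a [cohort_config()].
#' @param spectral a [spectral_config()].
#' @param scheme a [band_scheme()].
#' @param alpha significance level for edge flags.
#' @param multiplicity `"none"` (default) or `"BH"`.
#' @param min_duration_s minimum retained duration per recording.
#' @param cutoff_k,asr_window_s,filter_low,filter_high preprocessing
#'   parameters, see [preprocess_recording()].
#' @param behavior_params behavioral simulation parameters, see
#'   [behavior_params()].
#' @return An object of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(),
                       spectral = spectral_config(),
                       scheme = band_scheme(),
                       alpha = 0.05,
                       multiplicity = c("none", "BH"),
                       min_duration_s = 60,
                       cutoff_k = 20, asr_window_s = 0.5,
                       filter_low = 0.5, filter_high = 46,
                       behavior_params = resteeg::behavior_params()) {
  multiplicity <- match.arg(multiplicity)
  structure(list(cohort = cohort, spectral = spectral, scheme = scheme,
                 alpha = alpha, multiplicity = multiplicity,
                 min_duration_s = min_duration_s, cutoff_k = cutoff_k,
                 asr_window_s = asr_window_s, filter_low = filter_low,
                 filter_high = filter_high,
                 behavior_params = behavior_params),
            class = "run_config")
}

#' Validate a run configuration
#'
#' Checks band coverage, Nyquist limits, cohort size and parameter ranges;
#' returns human-readable problem descriptions instead of failing, so a
#' front end can report all problems at once.
#'
#' @param config a [run_config()].
#' @return Character vector of problems; empty when the configuration is
#'   valid.
#' @export
validate_config <- function(config) {
  problems <- character(0)
  add <- function(msg) problems <<- c(problems, msg)
  fs <- config$cohort$sample_rate
  nyq <- fs / 2
  for (bn in names(config$scheme$bands)) {
    if (config$scheme$bands[[bn]][2] > nyq)
      add(sprintf("band %s upper edge %g Hz exceeds Nyquist %g Hz",
                  bn, config$scheme$bands[[bn]][2], nyq))
  }
  if (config$filter_high >= nyq)
    add(sprintf("filter high corner %g Hz must be below Nyquist %g Hz",
                config$filter_high, nyq))
  if (config$cohort$n_subjects < 3)
    add("cohort needs at least 3 subjects for the correlation stage")
  if (config$cohort$duration_s < config$spectral$epoch_s)
    add("recording duration shorter than one spectral epoch")
  if (config$alpha <= 0 || config$alpha > 1)
    add("alpha must be in (0, 1]")
  if (config$spectral$overlap_s >= config$spectral$epoch_s)
    add("spectral overlap must be smaller than the epoch")
  problems
}

write_stage_csv <- function(df, dir, name, log) {
  path <- file.path(dir, name)
  utils::write.csv(df, path, row.names = FALSE)
  log(sprintf("wrote %s: %d rows", name, nrow(df)))
  path
}

#' Run the full pipeline
#'
#' simulate -> preprocess -> spectra -> coherence -> behavior -> correlate,
#' writing every stage table as CSV plus a JSON manifest with per-file
#' checksums, row counts, the seed and the package version. Identical
#' configurations produce identical checksums. Any stage error aborts the
#' run; already-written outputs are retained next to a `FAILED` manifest
#' naming the stage.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @param verbose print per-stage progress.
#' @return A `report_bundle`: list with `files` (named paths), `manifest`
#'   (parsed manifest) and the key result tables.
#' @export
run_pipeline <- function(config, out_dir, verbose = TRUE) {
  problems <- validate_config(config)
  if (length(problems) > 0)
    stop("invalid configuration:\n  ", paste(problems, collapse = "\n  "))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- function(msg) if (verbose) message("[resteeg] ", msg)
  files <- character(0)
  stage <- "simulate"
  result <- tryCatch({
    log("stage simulate")
    cohort <- generate_cohort(config$cohort)
    log(sprintf("simulated %d recordings, %d subjects",
                length(cohort$recordings), config$cohort$n_subjects))

    stage <- "preprocess"
    log("stage preprocess")
    cleaned <- list()
    reports <- list()
    for (nm in names(cohort$recordings)) {
      pp <- preprocess_recording(cohort$recordings[[nm]],
                                 low = config$filter_low,
                                 high = config$filter_high,
                                 cutoff_k = config$cutoff_k,
                                 window_s = config$asr_window_s,
                                 min_s = config$min_duration_s)
      cleaned[[nm]] <- pp$recording
      reports[[nm]] <- data.frame(
        recording = nm,
        channels_removed = paste(pp$report$channels_removed$channel,
                                 collapse = ";"),
        windows_reconstructed = pp$report$windows_reconstructed,
        retained_duration_s = pp$report$retained_duration_s,
        stringsAsFactors = FALSE)
    }
    cleaning <- do.call(rbind, reports)
    files["cleaning_report"] <- write_stage_csv(
      cleaning, out_dir, "cleaning_report.csv", log)

    stage <- "spectra"
    log("stage spectra")
    bp <- band_power_table(cleaned, config$scheme, config$spectral)
    files["band_power"] <- write_stage_csv(bp, out_dir, "band_power.csv",
                                           log)

    stage <- "coherence"
    log("stage coherence")
    edges <- coherence_edge_table(cleaned, config$scheme, config$spectral)
    files["coherence_edges"] <- write_stage_csv(
      edges, out_dir, "coherence_edges.csv", log)

    stage <- "behavior"
    log("stage behavior")
    behavior <- cohort$behavior
    files["behavior_covariates"] <- write_stage_csv(
      behavior, out_dir, "behavior_covariates.csv", log)
    sessions <- simulate_behavior_cohort(config$cohort$n_subjects,
                                         config$behavior_params,
                                         seed = config$cohort$master_seed)
    files["behavior_summary"] <- write_stage_csv(
      sessions, out_dir, "behavior_summary.csv", log)

    stage <- "correlate"
    log("stage correlate")
    maps <- list()
    edge_nets <- list()
    for (measure in c("mean_rt_ms", "accuracy_pct")) {
      cm <- correlation_map(bp, behavior, measure)
      files[paste0("correlation_map_", measure)] <- write_stage_csv(
        cm, out_dir, paste0("correlation_map_", measure, ".csv"), log)
      maps[[measure]] <- cm
      en <- edge_correlation_network(edges, behavior, measure,
                                     alpha = config$alpha,
                                     method = config$multiplicity)
      files[paste0("edge_correlation_", measure)] <- write_stage_csv(
        en, out_dir, paste0("edge_correlation_", measure, ".csv"), log)
      edge_nets[[measure]] <- en
    }
    contrast <- NULL
    if (all(c("eyes_closed", "eyes_open") %in% config$cohort$conditions)) {
      ct <- ec_eo_alpha_contrast(bp)
      contrast <- cbind(ct$summary,
                        data.frame(kw_H = ct$test$H, kw_p = ct$test$p))
      files["ec_eo_alpha_contrast"] <- write_stage_csv(
        contrast, out_dir, "ec_eo_alpha_contrast.csv", log)
    }
    list(band_power = bp, edges = edges, behavior = behavior,
         maps = maps, edge_networks = edge_nets, contrast = contrast,
         cleaning = cleaning)
  }, error = function(e) {
    manifest <- list(status = "FAILED", stage = stage,
                     error = conditionMessage(e),
                     files = as.list(files))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    stop("pipeline failed at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  })
  manifest <- list(
    status = "OK",
    package_version = as.character(utils::packageVersion("resteeg")),
    master_seed = config$cohort$master_seed,
    n_subjects = config$cohort$n_subjects,
    files = lapply(stats::setNames(nm = names(files)), function(k) {
      list(path = basename(files[[k]]),
           md5 = unname(tools::md5sum(files[[k]])),
           rows = nrow(utils::read.csv(files[[k]])))
    }))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  structure(c(result, list(files = files, manifest = manifest,
                           out_dir = out_dir)),
            class = "report_bundle")
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("<report_bundle> ", length(x$files), " files in ", x$out_dir, "\n",
      sep = "")
  for (k in names(x$manifest$files))
    cat(sprintf("  %-32s %6d rows  md5 %s\n",
                x$manifest$files[[k]]$path, x$manifest$files[[k]]$rows,
                substr(x$manifest$files[[k]]$md5, 1, 8)))
  invisible(x)
}

#' Load a run configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()], [cohort_config()] and
#' [spectral_config()]; unknown keys are rejected. Planted effects are
#' given as a list of `{channel(s), band, measure, rho}` records.
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("cohort", "spectral", "alpha", "multiplicity",
             "min_duration_s", "cutoff_k", "asr_window_s", "filter_low",
             "filter_high")
  unknown <- setdiff(names(y), known)
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  ccall <- y$cohort %||% list()
  if (!is.null(ccall$planted_effects)) {
    ccall$planted_effects <- lapply(ccall$planted_effects, function(e) {
      planted_effect(unlist(e$channel), e$band, e$measure, e$rho)
    })
  }
  if (!is.null(ccall$band_density))
    ccall$band_density <- unlist(ccall$band_density)
  cohort <- do.call(cohort_config, ccall)
  spectral <- do.call(spectral_config, y$spectral %||% list())
  args <- y[setdiff(names(y), c("cohort", "spectral"))]
  do.call(run_config, c(list(cohort = cohort, spectral = spectral), args))
}
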
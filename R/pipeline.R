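#' Default pipeline configuration
#'
#' A nested list with every tunable of the pipeline, serializable to JSON
#' with [write_run_config()].  Sections: `layout` (spots per image block
#' and geometry), `schedule` (spotting start, frequency, fraction count),
#' `image` (densitometry), `chromatogram` (smoothing and peak picking),
#' `features` (mass-trace finder), `correlation` (gating, threshold,
#' MS2 export).
#'
#' @return A `biospot_config` list.
#' @export
default_run_config <- function() {
  structure(list(
    layout = list(n_rows = 10L, n_cols = 10L, pitch = 20, spot_radius = 5,
                  block_rows = 10L, block_cols = 10L),
    schedule = list(t0 = 1.0, frequency = 1, n_fractions = 200L),
    image = list(invert = FALSE, measure_radius_factor = 0.8,
                 halo_weight = 1, k_mad = 5, min_contrast = 0.25),
    chromatogram = list(sigma = 1, min_prominence = 0.5,
                        min_width_fractions = 2L),
    features = list(ppm_tol = 10, min_trace_length = 5L, min_intensity = 0,
                    gap_scans = 1L, min_prominence_rel = 0.1),
    correlation = list(rt_bias = 0, rt_window = 10, r_threshold = 0.8,
                       min_overlap_points = 5L, mz_tol_ms2 = 0.01)
  ), class = "biospot_config")
}

#' Read / write a pipeline configuration file
#'
#' JSON round-trips losslessly; keys absent from the file keep their
#' defaults, and unknown keys are rejected with the offending name.
#'
#' @param config A `biospot_config` list.
#' @param path Config file path (JSON).
#' @return `write_run_config()` returns `path` invisibly;
#'   `read_run_config()` a validated `biospot_config`.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort_io("config file '%s' not found", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  def <- default_run_config()
  bad_sections <- setdiff(names(raw), names(def))
  if (length(bad_sections))
    abort_validation("unknown config section: %s",
                     paste(bad_sections, collapse = ", "))
  for (sec in names(raw)) {
    bad <- setdiff(names(raw[[sec]]), names(def[[sec]]))
    if (length(bad))
      abort_validation("unknown config key: %s",
                       paste(paste0(sec, ".", bad), collapse = ", "))
    for (k in names(raw[[sec]])) def[[sec]][[k]] <- raw[[sec]][[k]]
  }
  def
}

config_layout <- function(config) {
  pad_layout(config$layout$n_rows, config$layout$n_cols,
             pitch = config$layout$pitch,
             spot_radius = config$layout$spot_radius,
             block_shape = c(config$layout$block_rows,
                             config$layout$block_cols))
}

config_schedule <- function(config) {
  spotting_schedule(config$schedule$t0, config$schedule$frequency,
                    config$schedule$n_fractions)
}

config_correlation <- function(config) {
  correlation_config(config$correlation$rt_bias,
                     config$correlation$rt_window,
                     config$correlation$r_threshold,
                     config$correlation$min_overlap_points,
                     config$correlation$mz_tol_ms2)
}

#' Run the full bioactivity-correlation pipeline
#'
#' Chains image densitometry, chromatogram construction, peak detection,
#' LC-MS feature finding, retention-time gating, Pearson peak-shape
#' correlation, ranking and export.  Each image covers one layout block of
#' fractions in serpentine order (image order = fraction order).
#'
#' @param images Character vector of PNG paths, or a list of
#'   `intensity_image`/matrix objects.
#' @param mzml Path to an mzML file, or a `spectrum_series`.
#' @param config A `biospot_config`; see [default_run_config()].
#' @param out_dir Optional output directory; when given, writes
#'   `spots.csv`, `chromatogram.csv`, `peaks.csv`, `features.csv`,
#'   `ranked.csv`, `filtered.mzML` and `report.txt`.  On error all partial
#'   outputs are removed.
#' @param features Optional pre-computed `ms_features` table (e.g. from
#'   [read_feature_table()]); profiles missing from it are reconstructed
#'   from the run via XICs.
#' @param verbose Print per-stage progress (default `FALSE`).
#' @return List with `spots`, `chromatogram`, `peaks`, `features`,
#'   `results`, `ms2_kept` and `report` (named counts: spots, peaks,
#'   features, retained).
#' @export
run_pipeline <- function(images, mzml, config = default_run_config(),
                         out_dir = NULL, features = NULL, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  written <- character(0)
  emit <- function(fun, obj, name) {
    if (is.null(out_dir)) return(invisible(NULL))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- file.path(out_dir, name)
    fun(obj, p)
    written <<- c(written, p)
  }
  stage <- "setup"
  tryCatch({
    layout <- config_layout(config)
    schedule <- config_schedule(config)
    cfg <- config_correlation(config)
    if (is.character(mzml) && !file.exists(mzml))
      abort_io("mzML file '%s' not found", mzml)

    stage <- "image"
    say("stage image: %d image(s)", length(images))
    if (is.character(images)) images <- as.list(images)
    if (!is.list(images)) images <- list(images)
    block <- layout$n_rows * layout$n_cols
    tabs <- lapply(seq_along(images), function(b)
      analyze_upad_image(images[[b]], layout,
                         index_offset = (b - 1L) * block,
                         invert = isTRUE(config$image$invert),
                         measure_radius = config$image$measure_radius_factor *
                           layout$spot_radius,
                         halo_weight = config$image$halo_weight,
                         k_mad = config$image$k_mad,
                         min_contrast = config$image$min_contrast))
    spots <- merge_spot_tables(tabs)
    emit(write_spot_table, spots, "spots.csv")

    stage <- "chromatogram"
    chrom <- assign_retention_times(spots, schedule)
    chrom <- smooth_chromatogram(chrom, config$chromatogram$sigma)
    emit(write_chromatogram, chrom, "chromatogram.csv")
    peaks <- detect_activity_peaks(chrom,
                                   config$chromatogram$min_prominence,
                                   config$chromatogram$min_width_fractions)
    emit(write_activity_peaks, peaks, "peaks.csv")
    say("stage chromatogram: %d fractions, %d peak(s)", nrow(chrom),
        nrow(peaks))

    stage <- "features"
    series <- if (is.character(mzml)) read_mzml(mzml) else mzml
    if (is.null(features)) {
      features <- find_features(series,
                                ppm_tol = config$features$ppm_tol,
                                min_trace_length =
                                  config$features$min_trace_length,
                                min_intensity = config$features$min_intensity,
                                gap_scans = config$features$gap_scans,
                                min_prominence_rel =
                                  config$features$min_prominence_rel)
    }
    features <- fill_feature_profiles(features, series,
                                      config$features$ppm_tol)
    emit(write_feature_table, features, "features.csv")
    say("stage features: %d feature(s)", nrow(features))

    stage <- "correlation"
    results <- correlate_features(peaks, chrom, features, cfg)
    emit(export_results, results, "ranked.csv")
    ms2_kept <- NULL
    if (!is.null(out_dir)) {
      p <- file.path(out_dir, "filtered.mzML")
      ms2_kept <- suppressWarnings(
        filter_ms2_for_networking(series, results, features, cfg, p))
      written <- c(written, p)
    }
    say("stage correlation: %d retained pair(s)", nrow(results))

    report <- c(spots = nrow(spots), peaks = nrow(peaks),
                features = nrow(features), retained = nrow(results))
    if (!is.null(out_dir)) {
      p <- file.path(out_dir, "report.txt")
      writeLines(c("biospot pipeline report",
                   sprintf("%-10s %d", names(report), report)), p)
      written <- c(written, p)
    }
    list(spots = spots, chromatogram = chrom, peaks = peaks,
         features = features, results = results, ms2_kept = ms2_kept,
         report = report)
  }, biospot_error = function(e) {
    unlink(written)
    e$message <- sprintf("[stage %s] %s", stage, conditionMessage(e))
    stop(e)
  })
}
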
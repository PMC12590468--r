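#' Correlation configuration
#'
#' Parameters governing how LC-MS features are matched to bioactivity
#' peaks.  A feature and a peak may represent the same compound only when
#' their apexes agree up to a systematic bias (the split-flow path to the
#' ESI source and to the spotter differ by an instrument-specific,
#' user-calibratable delay) within a tolerance window; surviving pairs are
#' scored by Pearson peak-shape correlation and those above the threshold
#' kept.
#'
#' @param rt_bias Systematic apex offset in seconds, defined as
#'   `feature_apex - activity_apex` for a true co-elution; may be negative.
#'   Default 0.
#' @param rt_window Allowed `|offset - rt_bias|` in seconds.  Default 10.
#' @param r_threshold Minimum Pearson coefficient; retained results must be
#'   strictly above it.  Default 0.8.
#' @param min_overlap_points Minimum common samples for a correlation to
#'   count (default 5, never below 3).
#' @param mz_tol_ms2 Absolute m/z tolerance when matching MS2 precursors to
#'   retained features for export (default 0.01).
#' @return A `correlation_config` object.
#' @export
correlation_config <- function(rt_bias = 0, rt_window = 10,
                               r_threshold = 0.8, min_overlap_points = 5,
                               mz_tol_ms2 = 0.01) {
  if (!is_number(rt_window) || rt_window < 0)
    abort_validation("rt_window must be >= 0 (seconds)")
  if (!is_number(r_threshold) || r_threshold < -1 || r_threshold > 1)
    abort_validation("r_threshold must lie in [-1, 1]")
  if (!is_count(min_overlap_points) || min_overlap_points < 3)
    abort_validation("min_overlap_points must be an integer >= 3")
  if (!is_number(mz_tol_ms2) || mz_tol_ms2 <= 0)
    abort_validation("mz_tol_ms2 must be > 0")
  structure(list(rt_bias = rt_bias, rt_window = rt_window,
                 r_threshold = r_threshold,
                 min_overlap_points = as.integer(min_overlap_points),
                 mz_tol_ms2 = mz_tol_ms2),
            class = "correlation_config")
}

#' @export
print.correlation_config <- function(x, ...) {
  cat(sprintf(
    "<correlation_config> bias %g s, window %g s, r > %g, >= %d points, MS2 m/z tol %g\n",
    x$rt_bias, x$rt_window, x$r_threshold, x$min_overlap_points,
    x$mz_tol_ms2))
  invisible(x)
}

#' Retention-time gate for a feature / activity-peak pair
#'
#' Passes when the apex difference, corrected for the configured bias,
#' falls inside the window:
#' `|(feature_apex - peak_apex) * 60 - rt_bias| <= rt_window` (seconds).
#'
#' @param peak_apex_rt Activity peak apex (min).
#' @param feature_apex_rt Feature apex (min).  Both vectorized.
#' @param cfg A [correlation_config()].
#' @return Logical.
#' @export
gate_by_retention_time <- function(peak_apex_rt, feature_apex_rt, cfg) {
  abs((feature_apex_rt - peak_apex_rt) * 60 - cfg$rt_bias) <= cfg$rt_window
}

#' Pearson peak-shape correlation of a feature against an activity peak
#'
#' The evaluation grid is the chromatogram's fraction times inside the
#' activity peak's bounds (the coarser, fixed-rate signal stays on its own
#' samples).  The feature's elution profile is shifted by the configured
#' bias into the activity time frame, linearly interpolated onto that grid
#' (zero outside its own support), and correlated with the activity
#' values.  The correlation is undefined -- returned as `NA` and excluded
#' by [rank_features()] -- when either vector is constant or fewer than
#' `min_overlap_points` grid samples exist.
#'
#' @param peak One row of an `activity_peaks` table.
#' @param chrom The `activity_chromatogram` the peak came from.
#' @param feature One row of an `ms_features` table (profile required).
#' @param cfg A [correlation_config()].
#' @return List with `pearson_r` and `n_points`.
#' @export
correlate_shapes <- function(peak, chrom, feature, cfg) {
  prof <- feature$profile[[1]]
  if (is.null(prof) || !nrow(prof))
    abort_validation(
      "feature '%s' has no elution profile; reconstruct it with fill_feature_profiles()",
      feature$feature_id)
  sel <- chrom$rt >= peak$start_rt & chrom$rt <= peak$end_rt
  grid <- chrom$rt[sel]
  act <- chrom$activity[sel]
  n <- length(grid)
  if (n < cfg$min_overlap_points)
    return(list(pearson_r = NA_real_, n_points = n))
  ft <- prof$rt - cfg$rt_bias / 60   # feature profile in the activity frame
  fi <- approx(ft, prof$intensity, xout = grid, rule = 1)$y
  fi[is.na(fi)] <- 0
  if (sd(act) == 0 || sd(fi) == 0)
    return(list(pearson_r = NA_real_, n_points = n))
  list(pearson_r = cor(act, fi), n_points = n)
}

#' Gate and score all feature / activity-peak pairs
#'
#' Applies the retention-time gate to every combination of activity peak
#' and feature, scores the survivors with [correlate_shapes()], and ranks
#' them per activity peak with [rank_features()].
#'
#' @param peaks An `activity_peaks` table.
#' @param chrom The `activity_chromatogram`.
#' @param features An `ms_features` table with profiles.
#' @param cfg A [correlation_config()].
#' @return A `correlation_results` data.frame (see [rank_features()]),
#'   including only retained (above-threshold) results.
#' @export
correlate_features <- function(peaks, chrom, features, cfg) {
  rows <- list()
  for (p in seq_len(nrow(peaks))) {
    for (f in seq_len(nrow(features))) {
      if (!gate_by_retention_time(peaks$apex_rt[p], features$apex_rt[f], cfg))
        next
      sc <- correlate_shapes(peaks[p, ], chrom, features[f, ], cfg)
      rows[[length(rows) + 1L]] <- data.frame(
        peak_id = peaks$peak_id[p],
        activity_peak_apex_rt = peaks$apex_rt[p],
        activity_auc = peaks$auc[p],
        feature_id = features$feature_id[f],
        mz = features$mz[f],
        feature_apex_rt = features$apex_rt[f],
        rt_offset_s = (features$apex_rt[f] - peaks$apex_rt[p]) * 60,
        pearson_r = sc$pearson_r, n_points = sc$n_points,
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(rows)) do.call(rbind, rows) else empty_results()
  rank_features(res, cfg)
}

empty_results <- function() {
  data.frame(peak_id = integer(0), activity_peak_apex_rt = numeric(0),
             activity_auc = numeric(0), feature_id = character(0),
             mz = numeric(0), feature_apex_rt = numeric(0),
             rt_offset_s = numeric(0), pearson_r = numeric(0),
             n_points = integer(0), stringsAsFactors = FALSE)
}

#' Filter and rank correlation results
#'
#' Per activity peak, drops results at or below the Pearson threshold
#' (strictly "above 0.8" by default) or with undefined correlation, sorts
#' the remainder by descending Pearson r -- ties broken by smaller
#' absolute retention-time offset, then lower m/z -- and assigns 1-based
#' ranks.
#'
#' @param results Scored results as produced inside [correlate_features()].
#' @param cfg A [correlation_config()].
#' @return A `correlation_results` data.frame with a `rank` column,
#'   ordered by `(activity_peak_apex_rt, rank)`.
#' @export
rank_features <- function(results, cfg) {
  res <- as.data.frame(results)
  res <- res[!is.na(res$pearson_r) & res$pearson_r > cfg$r_threshold &
               res$n_points >= cfg$min_overlap_points, , drop = FALSE]
  if (nrow(res)) {
    res <- res[order(res$peak_id, -res$pearson_r, abs(res$rt_offset_s),
                     res$mz), , drop = FALSE]
    res$rank <- unlist(lapply(split(seq_len(nrow(res)), res$peak_id),
                              seq_along), use.names = FALSE)
    res <- res[order(res$activity_peak_apex_rt, res$rank), , drop = FALSE]
  } else {
    res$rank <- integer(0)
  }
  rownames(res) <- NULL
  structure(res, class = c("correlation_results", "data.frame"))
}

#' @export
print.correlation_results <- function(x, ...) {
  cat(sprintf("<correlation_results> %d retained feature-peak pairs\n",
              nrow(x)))
  print.data.frame(head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat(sprintf("... %d more rows\n", nrow(x) - 10L))
  invisible(x)
}

#' Export ranked correlation results to CSV
#'
#' @param ranked A `correlation_results` table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_results <- function(ranked, path) {
  cols <- c("activity_peak_apex_rt", "activity_auc", "feature_id", "mz",
            "feature_apex_rt", "rt_offset_s", "pearson_r", "rank")
  df <- as.data.frame(ranked)[, cols, drop = FALSE]
  ok <- tryCatch({ write.csv(df, path, row.names = FALSE); TRUE },
                 error = function(e) FALSE)
  if (!ok) abort_io("cannot write results '%s'", path)
  invisible(path)
}

#' Read exported correlation results
#' @param path CSV written by [export_results()].
#' @return A `correlation_results` data.frame.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) abort_io("results file '%s' not found", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  structure(df, class = c("correlation_results", "data.frame"))
}

#' Filter MS2 scans for molecular networking
#'
#' Writes an mzML containing exactly those MS2 scans whose precursor m/z
#' lies within `mz_tol_ms2` of a retained feature's m/z and whose
#' retention time falls inside that feature's elution bounds, preserving
#' scan order.  This is the networking-ready output: only spectra that can
#' belong to a bioactivity-correlated compound survive.
#'
#' @param series The full run as a `spectrum_series`.
#' @param ranked Retained `correlation_results`.
#' @param features The `ms_features` table the results refer to.
#' @param cfg A [correlation_config()].
#' @param path Output mzML path.
#' @return Invisibly, the filtered `spectrum_series` that was written.
#' @export
filter_ms2_for_networking <- function(series, ranked, features, cfg, path) {
  stopifnot(inherits(series, "spectrum_series"))
  ids <- unique(ranked$feature_id)
  fsel <- features[features$feature_id %in% ids, , drop = FALSE]
  keep <- vapply(series$scans, function(s) {
    if (s$ms_level != 2L || !is_number(s$precursor_mz)) return(FALSE)
    any(abs(fsel$mz - s$precursor_mz) <= cfg$mz_tol_ms2 &
          s$rt >= fsel$start_rt & s$rt <= fsel$end_rt)
  }, logical(1))
  if (nrow(fsel) && !any(keep))
    warning("no MS2 scans matched the retained features", call. = FALSE)
  out <- new_spectrum_series(series$scans[keep], source = series$source)
  write_mzml(out, path)
  invisible(out)
}
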
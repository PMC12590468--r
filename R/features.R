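#' Extracted ion chromatogram
#'
#' For every MS1 scan, sums the intensities of centroid peaks within
#' `ppm_tol` parts-per-million of the target m/z; scans with no matching
#' peak contribute zero, so the XIC always spans the whole run.
#'
#' @param series A `spectrum_series`.
#' @param mz Target m/z.
#' @param ppm_tol Relative tolerance in ppm (default 10).
#' @return Data.frame `rt` (min), `intensity`, one row per MS1 scan.
#' @export
extract_xic <- function(series, mz, ppm_tol = 10) {
  stopifnot(inherits(series, "spectrum_series"))
  if (!is_number(ppm_tol) || ppm_tol <= 0)
    abort_validation("ppm_tol must be > 0")
  tol <- mz * ppm_tol * 1e-6
  sel <- scan_sel(series, 1L)
  rt <- numeric(length(sel)); ii <- numeric(length(sel))
  for (k in seq_along(sel)) {
    s <- series$scans[[sel[k]]]
    rt[k] <- s$rt
    hit <- abs(s$mz - mz) <= tol
    ii[k] <- if (any(hit)) sum(s$intensity[hit]) else 0
  }
  data.frame(rt = rt, intensity = ii)
}

#' Chain centroid peaks into mass traces
#'
#' Greedy trace building across consecutive MS1 scans: each peak at or
#' above `min_intensity` either extends the open trace whose running mean
#' m/z lies within `ppm_tol` (nearest match wins; ties go to the lower
#' m/z) or opens a new trace.  A trace missing from more than `gap_scans`
#' consecutive scans is closed; traces shorter than `min_trace_length`
#' scans are discarded.
#'
#' @param series A `spectrum_series` with centroided MS1 scans.
#' @param ppm_tol m/z tolerance in ppm (default 10).
#' @param min_trace_length Minimum number of scans in a kept trace
#'   (default 5).
#' @param min_intensity Centroid intensity floor (default 0; the
#'   trace-length filter does the work).
#' @param gap_scans Consecutive missed scans tolerated before a trace is
#'   closed (default 1).
#' @return List of `mass_trace` objects: data.frames `rt`, `mz`,
#'   `intensity` with attribute `mean_mz`, ordered by `mean_mz`.
#' @export
build_mass_traces <- function(series, ppm_tol = 10, min_trace_length = 5,
                              min_intensity = 0, gap_scans = 1) {
  stopifnot(inherits(series, "spectrum_series"))
  sel <- scan_sel(series, 1L)
  open <- list()   # each: mz_sum, n, miss, rt[], mz[], int[]
  done <- list()
  for (k in sel) {
    s <- series$scans[[k]]
    keep <- s$intensity >= min_intensity & s$intensity > 0
    pm <- s$mz[keep]; pint <- s$intensity[keep]
    ord <- order(pm)
    pm <- pm[ord]; pint <- pint[ord]
    matched_trace <- integer(0)
    matched_peak <- integer(0)
    if (length(open) && length(pm)) {
      tm <- vapply(open, function(tr) tr$mz_sum / tr$n, numeric(1))
      # candidate pairs within tolerance, matched greedily by |dppm|
      pairs <- do.call(rbind, lapply(seq_along(tm), function(ti) {
        d <- abs(pm - tm[ti]) / tm[ti] * 1e6
        ok <- which(d <= ppm_tol)
        if (!length(ok)) return(NULL)
        cbind(ti = ti, pi = ok, d = d[ok], pmz = pm[ok])
      }))
      if (!is.null(pairs)) {
        pairs <- pairs[order(pairs[, "d"], pairs[, "pmz"]), , drop = FALSE]
        used_t <- logical(length(open)); used_p <- logical(length(pm))
        for (r in seq_len(nrow(pairs))) {
          ti <- pairs[r, "ti"]; pi <- pairs[r, "pi"]
          if (used_t[ti] || used_p[pi]) next
          used_t[ti] <- TRUE; used_p[pi] <- TRUE
          matched_trace <- c(matched_trace, ti)
          matched_peak <- c(matched_peak, pi)
        }
      }
    }
    if (length(matched_trace)) for (j in seq_along(matched_trace)) {
      ti <- matched_trace[j]; pi <- matched_peak[j]
      tr <- open[[ti]]
      tr$mz_sum <- tr$mz_sum + pm[pi]; tr$n <- tr$n + 1L; tr$miss <- 0L
      tr$rt <- c(tr$rt, s$rt); tr$mz <- c(tr$mz, pm[pi])
      tr$int <- c(tr$int, pint[pi])
      open[[ti]] <- tr
    }
    # unmatched open traces age; close the expired ones
    if (length(open)) {
      aged <- setdiff(seq_along(open), matched_trace)
      for (ti in aged) open[[ti]]$miss <- open[[ti]]$miss + 1L
      expired <- vapply(open, function(tr) tr$miss > gap_scans, logical(1))
      done <- c(done, open[expired])
      open <- open[!expired]
    }
    # unmatched peaks open new traces
    for (pi in setdiff(seq_along(pm), matched_peak)) {
      open[[length(open) + 1L]] <- list(mz_sum = pm[pi], n = 1L, miss = 0L,
                                        rt = s$rt, mz = pm[pi],
                                        int = pint[pi])
    }
  }
  done <- c(done, open)
  done <- Filter(function(tr) tr$n >= min_trace_length, done)
  traces <- lapply(done, function(tr) {
    structure(data.frame(rt = tr$rt, mz = tr$mz, intensity = tr$int),
              class = c("mass_trace", "data.frame"),
              mean_mz = tr$mz_sum / tr$n)
  })
  traces[order(vapply(traces, attr, numeric(1), "mean_mz"))]
}

#' @export
print.mass_trace <- function(x, ...) {
  cat(sprintf("<mass_trace> m/z %.5f, %d scans, rt %.3f..%.3f min\n",
              attr(x, "mean_mz"), nrow(x), min(x$rt), max(x$rt)))
  invisible(x)
}

#' Detect elution peaks on a mass trace
#'
#' Prominence-based local maxima on the trace's intensity series; a
#' candidate apex is kept when its prominence reaches
#' `min_prominence_rel` times the trace's apex intensity.  Boundary maxima
#' count (a trace still rising at its last scan yields a feature with the
#' apex at that point).  Feature bounds sit at the prominence bases and the
#' elution profile is the trace between them.
#'
#' @param trace A `mass_trace`.
#' @param min_prominence_rel Relative prominence threshold (default 0.1).
#' @param id_prefix Prefix for generated feature ids.
#' @return An `ms_features` data.frame: `feature_id`, `mz`, `apex_rt`,
#'   `start_rt`, `end_rt`, `apex_intensity` and a `profile` list-column of
#'   `(rt, intensity)` data.frames.
#' @export
detect_feature_peaks <- function(trace, min_prominence_rel = 0.1,
                                 id_prefix = "F") {
  stopifnot(inherits(trace, "mass_trace"))
  y <- trace$intensity
  pk <- find_peaks_prominence(y, min_prominence = min_prominence_rel * max(y),
                              include_edges = TRUE)
  if (!nrow(pk)) return(empty_features())
  feats <- lapply(seq_len(nrow(pk)), function(k) {
    sel <- pk$left[k]:pk$right[k]
    prof <- data.frame(rt = trace$rt[sel], intensity = trace$intensity[sel])
    data.frame(feature_id = NA_character_, mz = attr(trace, "mean_mz"),
               apex_rt = trace$rt[pk$apex[k]],
               start_rt = trace$rt[pk$left[k]],
               end_rt = trace$rt[pk$right[k]],
               apex_intensity = max(prof$intensity),
               profile = I(list(prof)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, feats)
  out <- out[order(out$apex_rt), , drop = FALSE]
  out$feature_id <- sprintf("%s%03d", id_prefix, seq_len(nrow(out)))
  rownames(out) <- NULL
  structure(out, class = c("ms_features", "data.frame"))
}

empty_features <- function() {
  structure(data.frame(feature_id = character(0), mz = numeric(0),
                       apex_rt = numeric(0), start_rt = numeric(0),
                       end_rt = numeric(0), apex_intensity = numeric(0),
                       profile = I(list()), stringsAsFactors = FALSE),
            class = c("ms_features", "data.frame"))
}

#' @export
print.ms_features <- function(x, ...) {
  cat(sprintf("<ms_features> %d features\n", nrow(x)))
  df <- as.data.frame(x)
  df$profile <- NULL
  df$n_profile_points <- vapply(x$profile, nrow, integer(1))
  print.data.frame(head(df, 10))
  if (nrow(df) > 10) cat(sprintf("... %d more rows\n", nrow(df) - 10L))
  invisible(x)
}

#' Find LC-MS features in a spectrum series
#'
#' Convenience wrapper: [build_mass_traces()] then [detect_feature_peaks()]
#' per trace, with feature ids assigned across the whole run.
#'
#' @inheritParams build_mass_traces
#' @inheritParams detect_feature_peaks
#' @return An `ms_features` table sorted by m/z then apex retention time.
#' @export
find_features <- function(series, ppm_tol = 10, min_trace_length = 5,
                          min_intensity = 0, gap_scans = 1,
                          min_prominence_rel = 0.1) {
  traces <- build_mass_traces(series, ppm_tol, min_trace_length,
                              min_intensity, gap_scans)
  if (!length(traces)) return(empty_features())
  out <- do.call(rbind, lapply(traces, detect_feature_peaks,
                               min_prominence_rel = min_prominence_rel))
  out <- out[order(out$mz, out$apex_rt), , drop = FALSE]
  out$feature_id <- sprintf("F%03d", seq_len(nrow(out)))
  rownames(out) <- NULL
  structure(out, class = c("ms_features", "data.frame"))
}

#' Read / write a feature table CSV
#'
#' The CSV schema is `feature_id, mz, apex_rt, start_rt, end_rt,
#' apex_intensity` (retention times in minutes), the interoperability
#' surface towards external untargeted workflows.  Profiles are not stored
#' in the CSV; [fill_feature_profiles()] reconstructs them from the mzML
#' via XICs.
#'
#' @param path CSV path.
#' @param features An `ms_features` table.
#' @return `read_feature_table()` returns an `ms_features` table (empty
#'   profiles); `write_feature_table()` returns `path` invisibly.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) abort_io("feature table '%s' not found", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("feature_id", "mz", "apex_rt", "start_rt", "end_rt",
            "apex_intensity")
  miss <- setdiff(need, names(df))
  if (length(miss))
    abort_validation("feature table missing column(s): %s",
                     paste(miss, collapse = ", "))
  bad <- which(df$start_rt > df$end_rt | df$apex_rt < df$start_rt |
                 df$apex_rt > df$end_rt)
  if (length(bad))
    abort_validation("invalid retention-time bounds in row(s) %s",
                     paste(bad, collapse = ", "))
  df <- df[need]
  df$feature_id <- as.character(df$feature_id)
  df$profile <- I(rep(list(NULL), nrow(df)))
  structure(df, class = c("ms_features", "data.frame"))
}

#' @rdname read_feature_table
#' @export
write_feature_table <- function(features, path) {
  df <- as.data.frame(features)
  df$n_profile_points <- vapply(features$profile, function(p)
    if (is.null(p)) 0L else nrow(p), integer(1))
  df$profile <- NULL
  ok <- tryCatch({ write.csv(df, path, row.names = FALSE); TRUE },
                 error = function(e) FALSE)
  if (!ok) abort_io("cannot write feature table '%s'", path)
  invisible(path)
}

#' Reconstruct feature elution profiles from an mzML run
#'
#' For features imported via [read_feature_table()] (which carries no
#' profiles), fills each feature's profile with its XIC restricted to the
#' feature's retention-time bounds.
#'
#' @param features An `ms_features` table.
#' @param series The `spectrum_series` of the run.
#' @param ppm_tol XIC tolerance in ppm.
#' @return The features with profiles filled where they were missing.
#' @export
fill_feature_profiles <- function(features, series, ppm_tol = 10) {
  for (k in seq_len(nrow(features))) {
    if (!is.null(features$profile[[k]])) next
    xic <- extract_xic(series, features$mz[k], ppm_tol)
    sel <- xic$rt >= features$start_rt[k] & xic$rt <= features$end_rt[k]
    features$profile[[k]] <- xic[sel, , drop = FALSE]
  }
  features
}
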
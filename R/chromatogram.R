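#' Spotting schedule of a micro-fractionated run
#'
#' Records when spotting started relative to injection and how fast
#' fractions were collected.  At 1 Hz a 500-spot PAD covers 500 s
#' (8 min 20 s) of the LC run; the coverage window and per-fraction
#' deposited volume follow directly from these parameters.
#'
#' @param t0 Spotting start retention time (min).  Dead-time eluate before
#'   `t0` goes to waste and is simply absent from the chromatogram.
#' @param frequency Spotting frequency (fractions per second, Hz).
#' @param n_fractions Number of fractions collected.
#' @return A `spotting_schedule` object.
#' @export
spotting_schedule <- function(t0, frequency, n_fractions) {
  if (!is_number(t0) || t0 < 0) abort_validation("t0 must be >= 0 (min)")
  if (!is_number(frequency) || frequency <= 0)
    abort_validation("frequency must be > 0 (Hz)")
  if (!is_count(n_fractions) || n_fractions < 1)
    abort_validation("n_fractions must be a positive count")
  structure(list(t0 = t0, frequency = frequency,
                 n_fractions = as.integer(n_fractions)),
            class = "spotting_schedule")
}

#' @export
print.spotting_schedule <- function(x, ...) {
  cat(sprintf(
    "<spotting_schedule> %d fractions at %g Hz from %.3f min (covers %.1f s, to %.3f min)\n",
    x$n_fractions, x$frequency, x$t0, coverage_duration_s(x),
    x$t0 + x$n_fractions / (60 * x$frequency)))
  invisible(x)
}

#' Coverage duration of a schedule, in seconds
#' @param schedule A [spotting_schedule()].
#' @param n Number of fractions (defaults to the schedule's).
#' @return Seconds of LC run covered (`n / frequency`).
#' @export
coverage_duration_s <- function(schedule, n = schedule$n_fractions) {
  n / schedule$frequency
}

#' Coverage window of a schedule, in minutes
#' @inheritParams coverage_duration_s
#' @return `c(start, end)` retention times in minutes.
#' @export
coverage_window_min <- function(schedule, n = schedule$n_fractions) {
  c(schedule$t0, schedule$t0 + n / (60 * schedule$frequency))
}

#' Volume deposited per fraction
#'
#' With the LC flow split post-column (a T-piece sends a minor share to the
#' ESI source and the rest to the spotter), each fraction receives
#' `flow * split / frequency` of eluate: 1 mL/min with a 90% split at 1 Hz
#' deposits 15 uL per spot.
#'
#' @param flow_mL_min LC flow rate (mL/min).
#' @param split_to_spotter Fraction of the flow diverted to the spotter
#'   (0..1).
#' @param frequency Spotting frequency (Hz).
#' @return Deposited volume in microliters per fraction.
#' @export
fraction_volume_uL <- function(flow_mL_min, split_to_spotter, frequency) {
  if (split_to_spotter < 0 || split_to_spotter > 1)
    abort_validation("split_to_spotter must be within [0, 1]")
  flow_mL_min * split_to_spotter * 1000 / (60 * frequency)
}

#' Build a bioactivity chromatogram from a spot table
#'
#' Assigns each fraction its retention time from the spotting schedule.  A
#' fraction collected over `[t0 + i/f, t0 + (i+1)/f]` is represented by the
#' interval midpoint, `rt_i = t0 + (i + 0.5) / (60 f)` minutes, an unbiased
#' stamp for the 1/f-second collection window.
#'
#' @param table A normalized `spot_table` with contiguous serpentine
#'   indices 0..N-1.
#' @param schedule A [spotting_schedule()]; `N <= n_fractions`.
#' @return An `activity_chromatogram`: data.frame `rt` (min), `activity`
#'   (median-normalized), with attributes `sigma` (0 = unsmoothed),
#'   `frequency`, `t0`, `boundary_mode`.
#' @export
assign_retention_times <- function(table, schedule) {
  stopifnot(inherits(schedule, "spotting_schedule"))
  idx <- table$serpentine_index
  if (!identical(as.integer(sort(idx)), seq(0L, length(idx) - 1L)))
    abort_validation("serpentine indices must be contiguous 0..N-1")
  if (length(idx) > schedule$n_fractions)
    abort_validation("more spots (%d) than scheduled fractions (%d)",
                     length(idx), schedule$n_fractions)
  ord <- order(idx)
  act <- table$norm_activity[ord]
  if (all(is.na(act))) act <- table$raw_activity[ord]
  rt <- schedule$t0 + (idx[ord] + 0.5) / (60 * schedule$frequency)
  new_chromatogram(rt, act, sigma = 0, frequency = schedule$frequency,
                   t0 = schedule$t0)
}

new_chromatogram <- function(rt, activity, sigma, frequency, t0) {
  structure(data.frame(rt = rt, activity = activity),
            class = c("activity_chromatogram", "data.frame"),
            sigma = sigma, frequency = frequency, t0 = t0,
            boundary_mode = "reflect")
}

#' @export
print.activity_chromatogram <- function(x, ...) {
  cat(sprintf(
    "<activity_chromatogram> %d fractions, rt %.3f..%.3f min, sigma = %g\n",
    nrow(x), min(x$rt), max(x$rt), attr(x, "sigma")))
  invisible(x)
}

#' @export
plot.activity_chromatogram <- function(x, ...,
                                       xlab = "retention time (min)",
                                       ylab = "normalized bioactivity",
                                       type = "l") {
  graphics::plot(x$rt, x$activity, type = type, xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

# Discrete Gaussian kernel smoothing with 'reflect' boundary
# (d c b a | a b c d | d c b a), kernel truncated at 4 sigma and
# renormalized to unit sum so flat signals pass through unchanged.
gaussian_smooth <- function(x, sigma, truncate = 4) {
  if (sigma == 0) return(x)
  n <- length(x)
  r <- max(1L, as.integer(ceiling(truncate * sigma)))
  k <- dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  pad <- x[reflect_index(seq.int(1L - r, n + r), n)]
  out <- numeric(n)
  for (i in seq_len(n)) out[i] <- sum(k * pad[i:(i + 2L * r)])
  out
}

# Half-sample symmetric reflection (d c b a | a b c d | d c b a) for any
# integer index, tiling with period 2n.
reflect_index <- function(k, n) {
  j <- (k - 1L) %% (2L * n)
  ifelse(j < n, j + 1L, 2L * n - j)
}

#' Smooth a bioactivity chromatogram
#'
#' One-dimensional Gaussian kernel smoothing, sigma in fraction-index units
#' (so sigma = 1 at 1 Hz spans one second of elution).  The kernel is
#' truncated at 4 sigma and renormalized to unit sum; boundaries use
#' reflection, which preserves total signal for flat and symmetric traces.
#'
#' @param chrom An `activity_chromatogram`.
#' @param sigma Kernel width in fractions; 0 is the identity.  Default 1.
#' @return The smoothed chromatogram (the `sigma` attribute records the
#'   applied width).
#' @export
smooth_chromatogram <- function(chrom, sigma = 1) {
  stopifnot(inherits(chrom, "activity_chromatogram"))
  if (!is_number(sigma) || sigma < 0)
    abort_validation("sigma must be >= 0")
  out <- chrom
  out$activity <- gaussian_smooth(chrom$activity, sigma)
  attr(out, "sigma") <- attr(chrom, "sigma") + sigma
  out
}

# Prominence-based local-maximum finder shared by the bioactivity and
# LC-MS elution detectors.  Plateaus report their midpoint; with
# include_edges a boundary maximum (e.g. a rising trace cut off at the
# last scan) counts.  Bounds of a kept peak are the crossings of its
# prominence-base level (height - prominence) nearest the apex, clipped
# at the valley towards the adjacent kept peak, so a tall peak's base
# never swallows a lower neighbour.
find_peaks_prominence <- function(x, min_prominence = 0,
                                  include_edges = FALSE) {
  n <- length(x)
  empty <- data.frame(apex = integer(0), height = numeric(0),
                      prominence = numeric(0), left = integer(0),
                      right = integer(0))
  if (n < 2L) return(empty)
  apexes <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (x[i] > x[i - 1L]) {
      j <- i
      while (j < n && x[j + 1L] == x[j]) j <- j + 1L   # walk plateau
      if (j < n && x[j + 1L] < x[j]) {
        apexes <- c(apexes, as.integer((i + j) %/% 2L))
        i <- j + 1L
        next
      }
      i <- j + 1L
    } else i <- i + 1L
  }
  if (include_edges) {
    if (n >= 2L && x[1L] > x[2L]) apexes <- c(1L, apexes)
    if (n >= 2L && x[n] > x[n - 1L]) apexes <- c(apexes, n)
  }
  if (!length(apexes)) return(empty)
  h <- x[apexes]
  prom <- vapply(apexes, function(a) {
    li <- a
    while (li > 1L && x[li - 1L] <= x[a]) li <- li - 1L
    ri <- a
    while (ri < n && x[ri + 1L] <= x[a]) ri <- ri + 1L
    # only sides with extent count (an edge apex has one side)
    sides <- c(if (li < a) min(x[li:a]), if (ri > a) min(x[a:ri]))
    if (!length(sides)) return(0)
    x[a] - max(sides)
  }, numeric(1))
  keep <- prom > 0 & prom >= min_prominence
  apexes <- apexes[keep]; h <- h[keep]; prom <- prom[keep]
  K <- length(apexes)
  if (!K) return(empty)
  lb <- integer(K); rb <- integer(K)
  for (k in seq_len(K)) {
    a <- apexes[k]
    lo <- if (k > 1L) apexes[k - 1L] else 0L          # exclusive
    hi <- if (k < K) apexes[k + 1L] else n + 1L       # exclusive
    base <- h[k] - prom[k]
    l <- a
    while (l > lo + 1L && x[l] > base) l <- l - 1L
    if (x[l] > base && a > lo + 1L)
      l <- lo + which.min(x[(lo + 1L):a])             # valley to the left
    lb[k] <- l
    r <- a
    while (r < hi - 1L && x[r] > base) r <- r + 1L
    if (x[r] > base && hi - 1L > a)
      r <- a - 1L + which.min(x[a:(hi - 1L)])         # valley to the right
    rb[k] <- r
  }
  data.frame(apex = apexes, height = h, prominence = prom,
             left = lb, right = rb)
}

#' Detect peaks in a bioactivity chromatogram
#'
#' Local maxima with prominence at least `min_prominence` and base-to-base
#' width of at least `min_width_fractions` samples.  Peak bounds sit at the
#' prominence-base positions; AUC is the baseline-inclusive trapezoid of
#' activity vs retention time between the bounds.
#'
#' @param chrom A (smoothed) `activity_chromatogram`.  Unsmoothed input is
#'   accepted with a warning.
#' @param min_prominence Minimum prominence on the median-normalized
#'   activity scale (baseline around 1); default 0.5.
#' @param min_width_fractions Minimum width (samples between prominence
#'   bases); default 2.
#' @return An `activity_peaks` data.frame: `peak_id`, `apex_rt`,
#'   `start_rt`, `end_rt`, `height`, `prominence`, `auc`
#'   (activity x min), sorted by `apex_rt`.
#' @export
detect_activity_peaks <- function(chrom, min_prominence = 0.5,
                                  min_width_fractions = 2) {
  stopifnot(inherits(chrom, "activity_chromatogram"))
  if (attr(chrom, "sigma") == 0)
    warning("detecting peaks on an unsmoothed chromatogram", call. = FALSE)
  pk <- find_peaks_prominence(chrom$activity, min_prominence)
  pk <- pk[(pk$right - pk$left) >= min_width_fractions, , drop = FALSE]
  out <- data.frame(peak_id = integer(0), apex_rt = numeric(0),
                    start_rt = numeric(0), end_rt = numeric(0),
                    height = numeric(0), prominence = numeric(0),
                    auc = numeric(0))
  if (nrow(pk)) {
    auc <- vapply(seq_len(nrow(pk)), function(k) {
      sel <- pk$left[k]:pk$right[k]
      trapz(chrom$rt[sel], chrom$activity[sel])
    }, numeric(1))
    out <- data.frame(peak_id = seq_len(nrow(pk)),
                      apex_rt = chrom$rt[pk$apex],
                      start_rt = chrom$rt[pk$left],
                      end_rt = chrom$rt[pk$right],
                      height = pk$height, prominence = pk$prominence,
                      auc = auc)
    out <- out[order(out$apex_rt), , drop = FALSE]
    out$peak_id <- seq_len(nrow(out))
    rownames(out) <- NULL
  }
  structure(out, class = c("activity_peaks", "data.frame"))
}

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

#' Read / write chromatogram and peak CSVs
#' @param chrom An `activity_chromatogram`; `peaks` an `activity_peaks`.
#' @param peaks Peak table from [detect_activity_peaks()].
#' @param path Output CSV path.
#' @return `path` invisibly (writers); the object (readers).
#' @export
write_chromatogram <- function(chrom, path) {
  write.csv(data.frame(rt_min = chrom$rt, activity = chrom$activity),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_chromatogram
#' @export
read_chromatogram <- function(path) {
  if (!file.exists(path)) abort_io("chromatogram '%s' not found", path)
  df <- read.csv(path)
  if (!all(c("rt_min", "activity") %in% names(df)))
    abort_validation("chromatogram CSV needs rt_min and activity columns")
  step <- diff(df$rt_min)
  freq <- 1 / (60 * median(step))
  new_chromatogram(df$rt_min, df$activity, sigma = NA_real_,
                   frequency = freq, t0 = df$rt_min[1] - median(step) / 2)
}

#' @rdname write_chromatogram
#' @export
write_activity_peaks <- function(peaks, path) {
  write.csv(as.data.frame(peaks), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_chromatogram
#' @export
read_activity_peaks <- function(path) {
  if (!file.exists(path)) abort_io("peaks file '%s' not found", path)
  df <- read.csv(path)
  need <- c("apex_rt", "start_rt", "end_rt", "height", "prominence", "auc")
  miss <- setdiff(need, names(df))
  if (length(miss))
    abort_validation("peaks CSV missing column(s): %s",
                     paste(miss, collapse = ", "))
  if (is.null(df$peak_id)) df$peak_id <- seq_len(nrow(df))
  structure(df, class = c("activity_peaks", "data.frame"))
}
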
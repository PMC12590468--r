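# Shared fixture builders; everything is generated in code, no stored data.

# Small axis-aligned blob image: lattice of Gaussian spots, unit background.
blob_image <- function(n_rows, n_cols, pitch = 20, spot_radius = 5,
                       activities = rep(1, n_rows * n_cols), ...) {
  layout <- pad_layout(n_rows, n_cols, pitch = pitch,
                       spot_radius = spot_radius)
  generate_upad_image(layout, activities, ...)
}

# A chromatogram straight from numbers (bypasses the image stage).
chrom_from_activity <- function(activity, t0 = 1, frequency = 1) {
  tab <- data.frame(serpentine_index = seq_along(activity) - 1L,
                    norm_activity = activity,
                    raw_activity = activity)
  sched <- spotting_schedule(t0, frequency, length(activity))
  assign_retention_times(tab, sched)
}

# Gaussian activity bump(s) on a baseline of 1.
activity_with_peaks <- function(n, apex_idx, amp, sigma_fr = 3) {
  a <- rep(1, n)
  for (k in seq_along(apex_idx))
    a <- a + amp[k] * exp(-(seq_len(n) - apex_idx[k])^2 / (2 * sigma_fr^2))
  a
}

# Minimal in-memory MS1 series from a matrix of (rt, mz, intensity) peaks.
series_from_peaks <- function(rt, peaks_by_scan, ms2 = list()) {
  scans <- lapply(seq_along(rt), function(i) {
    p <- peaks_by_scan[[i]]
    list(rt = rt[i], ms_level = 1L, precursor_mz = NA_real_,
         mz = p$mz, intensity = p$intensity)
  })
  scans <- c(scans, ms2)
  ord <- order(vapply(scans, function(s) s$rt, numeric(1)))
  spectrum_series(scans[ord])
}

# Bare spot table with given raw activities (positions irrelevant).
as_spot_table_for_test <- function(raw, offset = 0L, source = "img1") {
  n <- length(raw)
  biospot:::as_spot_table(data.frame(
    serpentine_index = seq_len(n) - 1L + offset,
    label = paste0("A", seq_len(n) + offset),
    grid_row = 0L, grid_col = seq_len(n) - 1L + offset,
    center_x_px = NA_real_, center_y_px = NA_real_,
    mean_intensity = raw, halo_radius_px = NA_real_,
    raw_activity = raw, norm_activity = NA_real_,
    source_image = source, stringsAsFactors = FALSE))
}

# Direct textbook Pearson correlation (independent of stats::cor).
pearson_direct <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}
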
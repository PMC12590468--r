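as_spot_table <- function(df, normalization_median = NA_real_,
                          source_images = character(0)) {
  structure(df, class = c("spot_table", "data.frame"),
            normalization_median = normalization_median,
            source_images = source_images)
}

#' @export
print.spot_table <- function(x, ...) {
  med <- attr(x, "normalization_median")
  cat(sprintf("<spot_table> %d spots (indices %d..%d)%s\n", nrow(x),
              min(x$serpentine_index), max(x$serpentine_index),
              if (is.finite(med)) sprintf(", normalization median %.4g", med)
              else ", not normalized"))
  print.data.frame(head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

#' Mean pixel intensity of a spot
#'
#' Arithmetic mean over the pixels whose centers lie within
#' `measure_radius` of the spot center.  The measurement disk defaults to
#' 0.8 of the printed spot radius to avoid the wax rim.
#'
#' @param img `intensity_image` or matrix.
#' @param center Numeric `(x, y)` pixel coordinates.
#' @param measure_radius Disk radius in pixels.
#' @return Mean intensity (scalar).  Disks straddling the image edge are
#'   clipped with a warning; a disk entirely outside is an error.
#' @export
measure_spot_intensity <- function(img, center, measure_radius) {
  img <- as_intensity_image(img)
  sel <- disk_pixels(dim(img$pixels), center, measure_radius)
  if (sel$outside) abort_validation(
    "measurement disk at (%.1f, %.1f) lies entirely outside the image",
    center[1], center[2])
  if (sel$clipped)
    warning(sprintf("measurement disk at (%.1f, %.1f) clipped at image edge",
                    center[1], center[2]), call. = FALSE)
  mean(img$pixels[sel$idx])
}

# Pixel indices of a disk; pixel [i, j] sits at (x = j, y = i).
disk_pixels <- function(dims, center, radius) {
  cx <- center[1]; cy <- center[2]
  nr <- dims[1]; nc <- dims[2]
  i0 <- floor(cy - radius); i1 <- ceiling(cy + radius)
  j0 <- floor(cx - radius); j1 <- ceiling(cx + radius)
  clipped <- i0 < 1 || j0 < 1 || i1 > nr || j1 > nc
  ii <- max(1, i0):min(nr, i1); jj <- max(1, j0):min(nc, j1)
  if (i0 > nr || i1 < 1 || j0 > nc || j1 < 1)
    return(list(idx = integer(0), clipped = TRUE, outside = TRUE))
  g <- expand.grid(i = ii, j = jj)
  inside <- (g$j - cx)^2 + (g$i - cy)^2 <= radius^2
  idx <- (g$j[inside] - 1L) * nr + g$i[inside]
  list(idx = idx, clipped = clipped, outside = length(idx) == 0L)
}

#' Quantify the luminescent halo around a spot
#'
#' Sublethal compound concentrations in the diffusion gradient around an
#' inhibition zone light up as an annular halo.  The median radial intensity
#' profile is computed in 1-px annuli from `measure_radius` out to
#' `search_radius`; a halo is the outermost contiguous band of annuli whose
#' median exceeds `background + k_mad * scale`, where `scale` is a robust
#' (MAD-based) spread of the inter-spot background.  To distinguish a halo
#' from the tail of a bright spot, the band must be detached: the profile
#' has to drop below the threshold at least once beyond `measure_radius`
#' before the band begins.
#'
#' @param img `intensity_image` or matrix.
#' @param center `(x, y)` spot center in pixels.
#' @param measure_radius Inner radius (px) of the searched annulus, normally
#'   the measurement-disk radius.
#' @param search_radius Outer search limit (px), must exceed
#'   `measure_radius`.
#' @param background Background intensity level; estimate with
#'   [estimate_background()] over inter-spot pixels.
#' @param background_scale Robust spread of the background
#'   (`1.4826 * MAD`); same source.
#' @param k_mad Threshold multiplier (default 5).
#' @return Halo outer radius in px, or `NA_real_` when no halo is present
#'   (absence is a valid result).
#' @export
measure_halo <- function(img, center, measure_radius, search_radius,
                         background, background_scale, k_mad = 5) {
  img <- as_intensity_image(img)
  if (search_radius <= measure_radius)
    abort_validation("search_radius must exceed measure_radius")
  px <- img$pixels
  nr <- nrow(px); nc <- ncol(px)
  i0 <- max(1, floor(center[2] - search_radius))
  i1 <- min(nr, ceiling(center[2] + search_radius))
  j0 <- max(1, floor(center[1] - search_radius))
  j1 <- min(nc, ceiling(center[1] + search_radius))
  if (i0 > i1 || j0 > j1) return(NA_real_)
  g <- expand.grid(i = i0:i1, j = j0:j1)
  d <- sqrt((g$j - center[1])^2 + (g$i - center[2])^2)
  keep <- d >= measure_radius & d <= search_radius
  if (!any(keep)) return(NA_real_)
  v <- px[(g$j[keep] - 1L) * nr + g$i[keep]]
  ring <- floor(d[keep] - measure_radius)       # 1-px annuli
  prof <- tapply(v, ring, median)
  r_out <- measure_radius + as.numeric(names(prof)) + 1  # outer edge of annulus
  thr <- background + k_mad * background_scale
  above <- prof > thr
  if (!any(above)) return(NA_real_)
  # detached band: require at least one sub-threshold annulus before it
  first_below <- match(FALSE, above)
  if (is.na(first_below)) return(NA_real_)      # bright all the way out: spot tail
  band <- which(above & seq_along(above) > first_below)
  if (!length(band)) return(NA_real_)
  r_out[max(band)]
}

#' Estimate inter-spot background level and robust scale
#'
#' Median and `1.4826 * MAD` of the pixels farther than `exclude_radius`
#' from every lattice node.
#'
#' @param img `intensity_image` or matrix.
#' @param centers Two-column matrix of `(x, y)` node centers.
#' @param exclude_radius Exclusion radius around each node (px).
#' @return List with `background` and `scale`.
#' @export
estimate_background <- function(img, centers, exclude_radius) {
  img <- as_intensity_image(img)
  px <- img$pixels
  nr <- nrow(px); nc <- ncol(px)
  keep <- matrix(TRUE, nr, nc)
  for (k in seq_len(nrow(centers))) {
    sel <- disk_pixels(c(nr, nc), centers[k, ], exclude_radius)
    keep[sel$idx] <- FALSE
  }
  v <- px[keep]
  if (!length(v)) v <- as.vector(px)
  list(background = median(v), scale = 1.4826 * mad(v, constant = 1))
}

#' Combine luminescence and halo size into one activity score
#'
#' The detected bioactivity of a fraction is the sum of its luminescence
#' signal and its halo size.  The two are not commensurate (intensity vs
#' length), so the halo diameter is expressed in pitch units and scaled by
#' the image's median spot intensity before the sum:
#' `raw = mean_intensity + halo_weight * (2 * halo_radius / pitch) * scale`.
#' With `halo_weight = 0` (or no halo) this reduces to pure densitometry.
#'
#' @param mean_intensity Spot mean intensity.
#' @param halo_radius Halo radius in px, or `NA` when absent.
#' @param pitch Lattice pitch in px.
#' @param image_intensity_scale Median spot `mean_intensity` of the source
#'   image.
#' @param halo_weight Weight of the halo term (default 1).
#' @return Raw activity score (vectorized).
#' @export
compute_activity <- function(mean_intensity, halo_radius, pitch,
                             image_intensity_scale, halo_weight = 1) {
  halo_term <- ifelse(is.na(halo_radius), 0,
                      halo_weight * (2 * halo_radius / pitch) *
                        image_intensity_scale)
  mean_intensity + halo_term
}

#' Median-normalize a spot table
#'
#' Divides each spot's raw activity by the median raw activity of its source
#' image, making activity values comparable across images and samples.
#' Normalization is per image and must happen before tables from different
#' images are merged.
#'
#' @param table A `spot_table` with `raw_activity` filled in.
#' @return The table with `norm_activity` set; the per-image medians are
#'   recorded in the `normalization_median` attribute (named by image).
#' @export
normalize_by_median <- function(table) {
  if (!nrow(table) || all(!is.finite(table$raw_activity)))
    abort_validation("no finite raw_activity values to normalize")
  src <- table$source_image
  src[is.na(src)] <- "<memory>"
  meds <- tapply(table$raw_activity, src, median, na.rm = TRUE)
  if (any(meds <= 0))
    abort_validation("median raw activity is zero (blank image?)")
  table$norm_activity <- table$raw_activity / as.numeric(meds[src])
  attr(table, "normalization_median") <- meds
  table
}

#' Merge spot tables covering one PAD
#'
#' When a PAD is imaged in blocks, each image yields its own (already
#' normalized) spot table with an index offset; merging reassembles the full
#' fraction series.
#'
#' @param tables List of `spot_table`s whose serpentine index ranges are
#'   disjoint and contiguous after offsets.
#' @return A single `spot_table` ordered by `serpentine_index`.
#' @export
merge_spot_tables <- function(tables) {
  if (inherits(tables, "spot_table")) return(tables)
  stopifnot(is.list(tables), length(tables) >= 1L)
  if (length(tables) == 1L) return(tables[[1]])
  all_idx <- sort(unlist(lapply(tables, function(t) t$serpentine_index)))
  if (anyDuplicated(all_idx))
    abort_validation("serpentine index ranges overlap across tables")
  if (!identical(as.integer(all_idx),
                 seq(min(all_idx), max(all_idx))))
    abort_validation("serpentine index ranges leave gaps after merging")
  df <- do.call(rbind, lapply(tables, as.data.frame))
  df <- df[order(df$serpentine_index), , drop = FALSE]
  rownames(df) <- NULL
  as_spot_table(df,
    normalization_median = unlist(lapply(tables, attr, "normalization_median")),
    source_images = unlist(lapply(tables, attr, "source_images")))
}

#' Full densitometry of one uPAD image
#'
#' Chains spot detection, grid fitting, serpentine enumeration, per-spot
#' intensity and halo measurement, activity scoring and median
#' normalization into one call, returning the normalized spot table for the
#' fractions covered by this image.
#'
#' @param img Path to a PNG, an `intensity_image`, or a matrix.
#' @param layout A [pad_layout()] describing the spots in this image.
#' @param index_offset Serpentine index of this image's first fraction.
#' @param invert Passed to [load_luminescence_image()] for path input.
#' @param measure_radius Measurement disk radius (px); default
#'   `0.8 * spot_radius`.
#' @param halo_weight Weight of the halo term in [compute_activity()];
#'   0 disables halo scoring.
#' @param search_radius Halo search limit (px); default `0.45 * pitch` so
#'   neighbouring spots stay out of the annulus.
#' @param k_mad Halo threshold multiplier, see [measure_halo()].
#' @param min_contrast Passed to [detect_candidate_spots()].
#' @param corner_hints Passed to [fit_spot_grid()].
#' @param normalize Median-normalize before returning (default `TRUE`).
#' @return A normalized `spot_table` for this image.
#' @export
analyze_upad_image <- function(img, layout, index_offset = 0L,
                               invert = FALSE,
                               measure_radius = 0.8 * layout$spot_radius,
                               halo_weight = 1,
                               search_radius = 0.45 * layout$pitch,
                               k_mad = 5, min_contrast = 0.25,
                               corner_hints = NULL, normalize = TRUE) {
  from_path <- is.character(img)
  src <- if (from_path) img else "<memory>"
  img <- if (from_path) load_luminescence_image(img, invert = invert)
         else as_intensity_image(img, invert = invert)
  rr <- c(0.5, 1.6) * layout$spot_radius
  cand <- detect_candidate_spots(img, radius_range = rr,
                                 min_contrast = min_contrast)
  grid <- fit_spot_grid(cand, layout, corner_hints = corner_hints,
                        image_dim = dim(img$pixels))
  tab <- enumerate_spots(grid, layout, index_offset = index_offset)
  ctr <- cbind(tab$center_x_px, tab$center_y_px)
  tab$mean_intensity <- vapply(seq_len(nrow(tab)), function(k)
    measure_spot_intensity(img, ctr[k, ], measure_radius), numeric(1))
  bg <- estimate_background(img, ctr, exclude_radius = search_radius)
  if (halo_weight > 0) {
    tab$halo_radius_px <- vapply(seq_len(nrow(tab)), function(k)
      measure_halo(img, ctr[k, ], measure_radius, search_radius,
                   bg$background, bg$scale, k_mad = k_mad), numeric(1))
  }
  scale <- median(tab$mean_intensity)
  tab$raw_activity <- compute_activity(tab$mean_intensity, tab$halo_radius_px,
                                       layout$pitch, scale, halo_weight)
  tab$source_image <- src
  attr(tab, "source_images") <- src
  attr(tab, "grid_model") <- grid
  if (normalize) tab <- normalize_by_median(tab)
  tab
}

#' Read / write a spot table CSV
#'
#' @param table A `spot_table`.
#' @param path CSV path.
#' @return `write_spot_table()` returns `path` invisibly;
#'   `read_spot_table()` returns a `spot_table`.
#' @export
write_spot_table <- function(table, path) {
  df <- as.data.frame(table)
  ok <- tryCatch({ write.csv(df, path, row.names = FALSE, na = ""); TRUE },
                 error = function(e) FALSE)
  if (!ok) abort_io("cannot write spot table '%s'", path)
  invisible(path)
}

#' @rdname write_spot_table
#' @export
read_spot_table <- function(path) {
  if (!file.exists(path)) abort_io("spot table '%s' not found", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("serpentine_index", "label", "grid_row", "grid_col",
            "center_x_px", "center_y_px", "mean_intensity",
            "halo_radius_px", "raw_activity", "norm_activity", "source_image")
  miss <- setdiff(need, names(df))
  if (length(miss))
    abort_validation("spot table missing column(s): %s",
                     paste(miss, collapse = ", "))
  df$halo_radius_px <- as.numeric(df$halo_radius_px)
  as_spot_table(df[order(df$serpentine_index), , drop = FALSE],
                source_images = unique(df$source_image))
}
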
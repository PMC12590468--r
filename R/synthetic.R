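# Seeded synthetic fixtures: uPAD luminescence images and LC-MS runs that
# share planted compounds, so the whole pipeline is testable without any
# instrument data.  All generators are pure functions of (parameters, seed).

#' Describe a planted compound
#'
#' @param mz m/z of the (singly charged, positive-mode) ion.
#' @param apex_rt Elution apex (min).
#' @param elution_sigma Gaussian elution width (min); default 0.05
#'   (~3 s FWHM/2.35, matching narrow UHPLC peaks).
#' @param apex_intensity Apex MS1 intensity (arbitrary counts).
#' @param is_active Whether the compound induces the bioreporter.
#' @param activity_gain Activity units per unit of deposited ion intensity
#'   (intensity integrated over one 1/f-second fraction); default 4e-6,
#'   which puts a 1e6-count compound about 4 median-normalized units above
#'   baseline at its apex fraction.
#' @param ms2_template Optional data.frame `fragment_mz`, `rel_intensity`
#'   used when MS2 scans are emitted near the apex.
#' @return A `planted_compound` list.
#' @export
planted_compound <- function(mz, apex_rt, elution_sigma = 0.05,
                             apex_intensity = 1e6, is_active = FALSE,
                             activity_gain = 4e-6, ms2_template = NULL) {
  if (elution_sigma <= 0 || apex_intensity <= 0)
    abort_validation("elution_sigma and apex_intensity must be > 0")
  if (is_active && activity_gain <= 0)
    abort_validation("active compounds need activity_gain > 0")
  if (is.null(ms2_template))
    ms2_template <- data.frame(
      fragment_mz = mz * c(0.35, 0.55, 0.8),
      rel_intensity = c(0.4, 1.0, 0.6))
  structure(list(mz = mz, apex_rt = apex_rt, elution_sigma = elution_sigma,
                 apex_intensity = apex_intensity, is_active = is_active,
                 activity_gain = activity_gain,
                 ms2_template = ms2_template),
            class = "planted_compound")
}

#' Render a synthetic uPAD luminescence image
#'
#' Gaussian-profile bright spots on a (optionally rotated) lattice, with
#' optional annular halos around designated spots, a linear background
#' gradient and additive Gaussian shot-like noise clipped at zero.
#' Activities are given in serpentine order and map linearly onto blob
#' amplitude.
#'
#' @param layout A [pad_layout()] for this image.
#' @param activities Numeric vector of length `n_rows * n_cols` in
#'   serpentine order; 0 renders a dark (inactive) spot.
#' @param rotation_deg Lattice rotation about the image center (degrees).
#' @param noise_sd Additive Gaussian noise SD (image units).
#' @param background Constant background level (default 0.05).
#' @param background_gradient Left-to-right linear background ramp added
#'   on top (total rise across the image; default 0).
#' @param halos Optional data.frame with `index` (0-based serpentine
#'   position within this image), `r_inner`, `r_outer` (px), `amplitude`.
#' @param amp_per_activity Blob amplitude per activity unit (default
#'   0.06 so typical activities stay within an 8-bit PNG range).
#' @param margin Border around the lattice (px); default one pitch.
#' @param seed RNG seed; identical seeds give identical images.
#' @return List with `image` (an `intensity_image`) and `truth`
#'   (centers in serpentine order, activities, halos, parameters).
#' @export
generate_upad_image <- function(layout, activities, rotation_deg = 0,
                                noise_sd = 0.01, background = 0.05,
                                background_gradient = 0, halos = NULL,
                                amp_per_activity = 0.06,
                                margin = layout$pitch, seed = NULL) {
  stopifnot(inherits(layout, "pad_layout"))
  if (length(activities) != layout$n_rows * layout$n_cols)
    abort_validation("activities must have length n_rows * n_cols")
  if (noise_sd < 0) abort_validation("noise_sd must be >= 0")
  with_seed(seed, {
    ord <- serpentine_order(layout$n_rows, layout$n_cols)
    p <- layout$pitch
    w <- 2 * margin + (layout$n_cols - 1) * p
    h <- 2 * margin + (layout$n_rows - 1) * p
    nc <- as.integer(ceiling(w)); nr <- as.integer(ceiling(h))
    cx0 <- margin + ord$grid_col * p
    cy0 <- margin + ord$grid_row * p
    th <- rotation_deg * pi / 180
    mx <- (nc + 1) / 2; my <- (nr + 1) / 2
    cx <- mx + cos(th) * (cx0 - mx) - sin(th) * (cy0 - my)
    cy <- my + sin(th) * (cx0 - mx) + cos(th) * (cy0 - my)
    px <- matrix(background, nr, nc) +
      matrix(background_gradient * (seq_len(nc) - 1) / max(1, nc - 1),
             nr, nc, byrow = TRUE)
    sig <- layout$spot_radius / 2
    add_blob <- function(cxk, cyk, A, sigk) {
      rad <- ceiling(3.5 * sigk)
      ii <- max(1, floor(cyk - rad)):min(nr, ceiling(cyk + rad))
      jj <- max(1, floor(cxk - rad)):min(nc, ceiling(cxk + rad))
      d2 <- outer((ii - cyk)^2, (jj - cxk)^2, "+")
      px[ii, jj] <<- px[ii, jj] + A * exp(-d2 / (2 * sigk^2))
    }
    for (k in seq_along(activities)) {
      if (activities[k] > 0)
        add_blob(cx[k], cy[k], amp_per_activity * activities[k], sig)
    }
    if (!is.null(halos)) for (hk in seq_len(nrow(halos))) {
      k <- halos$index[hk] + 1L
      rad <- ceiling(halos$r_outer[hk]) + 1L
      ii <- max(1, floor(cy[k] - rad)):min(nr, ceiling(cy[k] + rad))
      jj <- max(1, floor(cx[k] - rad)):min(nc, ceiling(cx[k] + rad))
      d <- sqrt(outer((ii - cy[k])^2, (jj - cx[k])^2, "+"))
      ring <- d >= halos$r_inner[hk] & d <= halos$r_outer[hk]
      px[ii, jj][ring] <- px[ii, jj][ring] + halos$amplitude[hk]
    }
    if (noise_sd > 0) px <- px + matrix(rnorm(nr * nc, 0, noise_sd), nr, nc)
    px <- pmax(px, 0)
    list(image = as_intensity_image(px),
         truth = list(layout = layout,
                      centers = data.frame(serpentine_index =
                                             ord$serpentine_index,
                                           x = cx, y = cy),
                      activities = activities, halos = halos,
                      rotation_deg = rotation_deg, noise_sd = noise_sd,
                      background = background,
                      amp_per_activity = amp_per_activity, seed = seed))
  })
}

gaussian_profile <- function(t, apex, sigma, amp) {
  amp * exp(-(t - apex)^2 / (2 * sigma^2))
}

# Integral of a compound's elution profile over [a, b] minutes, expressed
# in intensity-seconds (closed form via the normal CDF).
elution_integral_s <- function(compound, a, b) {
  with(compound, apex_intensity * elution_sigma * sqrt(2 * pi) * 60 *
         (pnorm((b - apex_rt) / elution_sigma) -
            pnorm((a - apex_rt) / elution_sigma)))
}

#' Generate a synthetic LC-MS run
#'
#' MS1 scans at a fixed rate with every compound contributing a Gaussian
#' elution profile at its m/z, plus seeded decoy compounds with random
#' m/z, apex and width.  MS2 scans are emitted near each compound's apex
#' from its fragment template.  Decoy apexes keep a minimum retention-time
#' separation from active compounds (shape-uncorrelated world) and decoy
#' m/z values stay tolerance-disjoint.
#'
#' @param compounds List of [planted_compound()]s.
#' @param rt_span `c(start, end)` of the run (min); default `c(0, 5)`.
#' @param scan_rate MS1 rate (Hz); default 1.
#' @param noise Multiplicative intensity noise SD (default 0).
#' @param n_decoys Number of decoy compounds (default 0).
#' @param seed RNG seed.
#' @param ms2_per_compound MS2 scans emitted around each apex (default 3).
#' @param min_decoy_rt_sep Minimum |decoy apex - active apex| (min);
#'   default 0.5 (30 s).
#' @param mz_range Decoy m/z range; decoys keep >= 0.5 m/z mutual spacing.
#' @param decoy_intensity Range of decoy apex intensities.
#' @param path Optional mzML output path.
#' @return List with `series` (a `spectrum_series`) and `truth`
#'   (all compounds including decoys, scan times, parameters).
#' @export
generate_lcms_run <- function(compounds, rt_span = c(0, 5), scan_rate = 1,
                              noise = 0, n_decoys = 0, seed = NULL,
                              ms2_per_compound = 3, min_decoy_rt_sep = 0.5,
                              mz_range = c(150, 1000),
                              decoy_intensity = c(2e5, 2e6), path = NULL) {
  if (scan_rate <= 0) abort_validation("scan_rate must be > 0 Hz")
  for (cp in compounds)
    if (cp$apex_rt < rt_span[1] || cp$apex_rt > rt_span[2])
      abort_validation("compound apex %.3f min outside rt_span", cp$apex_rt)
  with_seed(seed, {
    active_rts <- vapply(Filter(function(c) c$is_active, compounds),
                         function(c) c$apex_rt, numeric(1))
    all_mz <- vapply(compounds, function(c) c$mz, numeric(1))
    decoys <- list()
    while (length(decoys) < n_decoys) {
      mz <- runif(1, mz_range[1], mz_range[2])
      if (length(all_mz) && min(abs(all_mz - mz)) < 0.5) next
      apex <- runif(1, rt_span[1] + 0.15, rt_span[2] - 0.15)
      if (length(active_rts) && min(abs(active_rts - apex)) < min_decoy_rt_sep)
        next
      all_mz <- c(all_mz, mz)
      decoys[[length(decoys) + 1L]] <- planted_compound(
        mz = mz, apex_rt = apex,
        elution_sigma = runif(1, 0.03, 0.08),
        apex_intensity = runif(1, decoy_intensity[1], decoy_intensity[2]),
        is_active = FALSE)
    }
    all_cp <- c(compounds, decoys)
    ms1_rt <- seq(rt_span[1], rt_span[2], by = 1 / (60 * scan_rate))
    scans <- lapply(ms1_rt, function(t) {
      mzv <- numeric(0); iv <- numeric(0)
      for (cp in all_cp) {
        I <- gaussian_profile(t, cp$apex_rt, cp$elution_sigma,
                              cp$apex_intensity)
        if (I > 1e-6 * cp$apex_intensity) {
          if (noise > 0) I <- max(0, I * (1 + rnorm(1, 0, noise)))
          mzv <- c(mzv, cp$mz); iv <- c(iv, I)
        }
      }
      ord <- order(mzv)
      list(rt = t, ms_level = 1L, precursor_mz = NA_real_,
           mz = mzv[ord], intensity = iv[ord])
    })
    ms2 <- list()
    for (cp in all_cp) {
      if (ms2_per_compound < 1 || is.null(cp$ms2_template)) next
      offs <- seq_len(ms2_per_compound) - (ms2_per_compound + 1) / 2
      for (o in offs) {
        t <- cp$apex_rt + o * 0.4 / (60 * scan_rate)
        if (t < rt_span[1] || t > rt_span[2]) next
        ms2[[length(ms2) + 1L]] <- list(
          rt = t, ms_level = 2L, precursor_mz = cp$mz,
          mz = cp$ms2_template$fragment_mz,
          intensity = cp$ms2_template$rel_intensity * cp$apex_intensity / 10)
      }
    }
    scans <- c(scans, ms2)
    ord <- order(vapply(scans, function(s) s$rt, numeric(1)))
    series <- new_spectrum_series(scans[ord], source = "<synthetic>")
    if (!is.null(path)) write_mzml(series, path)
    list(series = series,
         truth = list(compounds = all_cp, ms1_rt = ms1_rt,
                      scan_rate = scan_rate, rt_span = rt_span,
                      noise = noise, seed = seed))
  })
}

#' Generate a linked uPAD + LC-MS dataset
#'
#' The end-to-end fixture: active compounds drive both the LC-MS run and
#' the bioactivity trace.  Each fraction's activity is the median-scale
#' baseline (1) plus, per active compound, `activity_gain` times the
#' compound's elution intensity integrated over that fraction's
#' `1/frequency`-second collection interval, shifted by the configured
#' spotter-vs-detector bias; seeded multiplicative noise is applied and the
#' activities are rendered into one image per layout block.
#'
#' @param compounds List of [planted_compound()]s (at least the active
#'   ones).
#' @param layout A [pad_layout()] for one image block (e.g. 10 x 10).
#' @param schedule A [spotting_schedule()]; `n_fractions` must be a
#'   multiple of the block size.
#' @param assay_noise Multiplicative activity noise SD (default 0.05).
#' @param rt_bias Feature-apex minus activity-apex offset (s; default 0).
#' @param n_decoys Decoy compounds in the MS run (default 20).
#' @param ms_noise Multiplicative MS intensity noise SD (default 0.02).
#' @param image_noise_sd Image noise SD (default 0.008).
#' @param scan_rate MS1 rate (Hz; default 1).
#' @param seed RNG seed.
#' @return List with `images` (list of `intensity_image`), `image_truths`,
#'   `series` (the LC-MS run), and `truth` (compounds incl. decoys,
#'   per-fraction activities, schedule, bias, seed).
#' @export
generate_linked_dataset <- function(compounds, layout, schedule,
                                    assay_noise = 0.05, rt_bias = 0,
                                    n_decoys = 20, ms_noise = 0.02,
                                    image_noise_sd = 0.008, scan_rate = 1,
                                    seed = NULL) {
  stopifnot(inherits(layout, "pad_layout"),
            inherits(schedule, "spotting_schedule"))
  block <- layout$n_rows * layout$n_cols
  N <- schedule$n_fractions
  if (N %% block != 0)
    abort_validation("n_fractions (%d) must be a multiple of the block size (%d)",
                     N, block)
  active <- Filter(function(c) c$is_active, compounds)
  win <- coverage_window_min(schedule)
  for (cp in active)
    if (cp$apex_rt - 3 * cp$elution_sigma < win[1] ||
        cp$apex_rt + 3 * cp$elution_sigma > win[2])
      warning(sprintf(
        "active compound at %.3f min is not fully inside the spotted window [%.3f, %.3f]",
        cp$apex_rt, win[1], win[2]), call. = FALSE)
  with_seed(seed, {
    f <- schedule$frequency
    i <- seq_len(N) - 1L
    lo <- schedule$t0 + i / (60 * f) + rt_bias / 60
    hi <- schedule$t0 + (i + 1) / (60 * f) + rt_bias / 60
    act <- rep(1, N)
    for (cp in active)
      act <- act + cp$activity_gain * elution_integral_s(cp, lo, hi)
    act_true <- act
    if (assay_noise > 0)
      act <- pmax(0.01, act * (1 + rnorm(N, 0, assay_noise)))
    n_img <- N %/% block
    images <- vector("list", n_img)
    image_truths <- vector("list", n_img)
    for (b in seq_len(n_img)) {
      sl <- act[((b - 1L) * block + 1L):(b * block)]
      g <- generate_upad_image(layout, sl, noise_sd = image_noise_sd,
                               seed = NULL)  # shares the outer RNG stream
      images[[b]] <- g$image
      image_truths[[b]] <- g$truth
    }
    run_span <- c(max(0, win[1] - 0.25), win[2] + 0.25)
    run <- generate_lcms_run(compounds, rt_span = run_span,
                             scan_rate = scan_rate, noise = ms_noise,
                             n_decoys = n_decoys, seed = NULL)
    list(images = images, image_truths = image_truths,
         series = run$series,
         truth = list(compounds = run$truth$compounds,
                      active_mz = vapply(active, function(c) c$mz,
                                         numeric(1)),
                      activities = act, activities_noiseless = act_true,
                      schedule = schedule, layout = layout,
                      rt_bias = rt_bias, assay_noise = assay_noise,
                      seed = seed))
  })
}

#' Write a complete synthetic dataset to disk
#'
#' Writes the block images as PNG, the run as mzML and the ground truth as
#' JSON -- the file-level inputs the pipeline (and its command-line
#' interface) consume.
#'
#' @param dataset Result of [generate_linked_dataset()].
#' @param dir Output directory (created if needed).
#' @return Named list of written paths.
#' @export
write_linked_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  img_paths <- character(length(dataset$images))
  for (b in seq_along(dataset$images)) {
    img_paths[b] <- file.path(dir, sprintf("pad_block_%02d.png", b))
    write_luminescence_image(dataset$images[[b]], img_paths[b])
  }
  mzml_path <- file.path(dir, "run.mzML")
  write_mzml(dataset$series, mzml_path)
  truth_path <- file.path(dir, "truth.json")
  tr <- dataset$truth
  jsonlite::write_json(list(
    seed = tr$seed, rt_bias = tr$rt_bias, assay_noise = tr$assay_noise,
    schedule = tr$schedule[c("t0", "frequency", "n_fractions")],
    layout = tr$layout[c("n_rows", "n_cols", "pitch", "spot_radius")],
    active_mz = tr$active_mz,
    compounds = lapply(tr$compounds, function(c)
      c[c("mz", "apex_rt", "elution_sigma", "apex_intensity",
          "is_active")]),
    activities = tr$activities), truth_path, auto_unbox = TRUE, digits = NA)
  list(images = img_paths, mzml = mzml_path, truth = truth_path)
}

#' The three-antibiotics fixture preset
#'
#' A validation-mixture-style run: three active compounds with distinct
#' retention times and one bioreporter readout, 200 fractions at 1 Hz
#' starting at 1.00 min (so the spotted window covers 1.00--4.33 min),
#' imaged as two 10 x 10 blocks.
#'
#' @param seed RNG seed.
#' @param n_decoys Decoy features in the MS run (default 20).
#' @param assay_noise Activity noise SD (default 0.05).
#' @param rt_bias Spotter/detector apex offset in seconds (default 0).
#' @return As [generate_linked_dataset()].
#' @export
three_antibiotics_preset <- function(seed = 1, n_decoys = 20,
                                     assay_noise = 0.05, rt_bias = 0) {
  compounds <- list(
    planted_compound(mz = 332.14, apex_rt = 1.80, elution_sigma = 0.040,
                     apex_intensity = 1.2e6, is_active = TRUE),
    planted_compound(mz = 402.18, apex_rt = 2.60, elution_sigma = 0.045,
                     apex_intensity = 1.0e6, is_active = TRUE),
    planted_compound(mz = 291.15, apex_rt = 3.50, elution_sigma = 0.050,
                     apex_intensity = 0.8e6, is_active = TRUE))
  layout <- pad_layout(10, 10, pitch = 20, spot_radius = 5)
  schedule <- spotting_schedule(t0 = 1.0, frequency = 1, n_fractions = 200)
  generate_linked_dataset(compounds, layout, schedule,
                          assay_noise = assay_noise, rt_bias = rt_bias,
                          n_decoys = n_decoys, seed = seed)
}
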
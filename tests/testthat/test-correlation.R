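# A peak/chromatogram/feature trio where the feature's elution profile
# generated the activity trace (plus optional noise).
linked_pair <- function(noise_sd = 0, seed = 1, bias_s = 0) {
  withr::with_seed(seed, {
    n <- 120
    apex <- 60
    prof_shape <- exp(-(seq_len(n) - apex)^2 / (2 * 4^2))
    act <- 1 + 3 * prof_shape
    if (noise_sd > 0) act <- act * (1 + rnorm(n, 0, noise_sd))
    chrom <- smooth_chromatogram(chrom_from_activity(act), 1)
    peaks <- detect_activity_peaks(chrom)
    rt <- chrom$rt + bias_s / 60
    feat <- structure(data.frame(
      feature_id = "F001", mz = 400.2,
      apex_rt = rt[apex], start_rt = rt[apex - 15], end_rt = rt[apex + 15],
      apex_intensity = 8e5,
      profile = I(list(data.frame(rt = rt, intensity = 8e5 * prof_shape)))),
      class = c("ms_features", "data.frame"))
    list(chrom = chrom, peaks = peaks, feature = feat)
  })
}

test_that("the retention-time gate applies bias and window in seconds", {
  cfg <- correlation_config(rt_bias = 0, rt_window = 10)
  expect_true(gate_by_retention_time(2.0, 2.0, cfg))
  expect_false(gate_by_retention_time(2.0, 2.5, cfg))   # 30 s late
  cfg2 <- correlation_config(rt_bias = 10, rt_window = 5)
  expect_true(gate_by_retention_time(2.0, 2.0 + 12 / 60, cfg2))  # |12-10|<=5
  expect_false(gate_by_retention_time(2.0, 2.0 + 16 / 60, cfg2))

  # brute-force interval-membership equivalence over a parameter grid
  for (bias in c(-20, 0, 15)) for (win in c(0, 5, 30)) {
    cfg3 <- correlation_config(rt_bias = bias, rt_window = win)
    for (off_s in seq(-40, 40, by = 2.5)) {
      feature_rt <- 2 + off_s / 60
      off_eff <- (feature_rt - 2) * 60
      inside <- off_eff >= bias - win && off_eff <= bias + win
      expect_identical(
        gate_by_retention_time(2, feature_rt, cfg3), inside)
    }
  }
})

test_that("peak-shape correlation is exact for proportional and affine profiles", {
  lp <- linked_pair(noise_sd = 0)
  cfg <- correlation_config()
  sel <- lp$chrom$rt >= lp$peaks$start_rt[1] & lp$chrom$rt <= lp$peaks$end_rt[1]
  grid_act <- lp$chrom$activity[sel]

  # profile exactly proportional to the on-grid activity -> r = 1
  f <- lp$feature
  f$profile[[1]] <- data.frame(rt = lp$chrom$rt,
                               intensity = 7.3 * lp$chrom$activity)
  r <- correlate_shapes(lp$peaks[1, ], lp$chrom, f[1, ], cfg)
  expect_equal(r$pearson_r, 1.0, tolerance = 1e-12)

  # affine decreasing transform -> r = -1 (dropped by the threshold)
  f$profile[[1]]$intensity <- 10 - 2 * lp$chrom$activity
  r2 <- correlate_shapes(lp$peaks[1, ], lp$chrom, f[1, ], cfg)
  expect_equal(r2$pearson_r, -1.0, tolerance = 1e-12)

  # constant profile: correlation undefined, excluded not zero
  f$profile[[1]]$intensity <- rep(4, nrow(f$profile[[1]]))
  r3 <- correlate_shapes(lp$peaks[1, ], lp$chrom, f[1, ], cfg)
  expect_true(is.na(r3$pearson_r))

  # missing profile instructs reconstruction
  f$profile <- I(list(NULL))
  expect_error(correlate_shapes(lp$peaks[1, ], lp$chrom, f[1, ], cfg),
               "fill_feature_profiles")
})

test_that("a co-eluting feature with 5% noise correlates above 0.95", {
  cfg <- correlation_config()
  for (seed in 1:5) {
    lp <- linked_pair(noise_sd = 0.05, seed = seed)
    r <- correlate_shapes(lp$peaks[1, ], lp$chrom, lp$feature[1, ], cfg)
    expect_gt(r$pearson_r, 0.95)
    # cross-check against the direct textbook formula on the same vectors
    sel <- lp$chrom$rt >= lp$peaks$start_rt[1] &
      lp$chrom$rt <= lp$peaks$end_rt[1]
    grid <- lp$chrom$rt[sel]
    fi <- approx(lp$feature$profile[[1]]$rt,
                 lp$feature$profile[[1]]$intensity, xout = grid, rule = 1)$y
    fi[is.na(fi)] <- 0
    expect_equal(r$pearson_r, pearson_direct(lp$chrom$activity[sel], fi),
                 tolerance = 1e-12)
  }
})

test_that("a configured bias realigns a shifted feature profile", {
  lp <- linked_pair(noise_sd = 0, bias_s = 12)
  gate_cfg <- correlation_config(rt_bias = 12, rt_window = 5)
  expect_true(gate_by_retention_time(lp$peaks$apex_rt[1],
                                     lp$feature$apex_rt[1], gate_cfg))
  r_biased <- correlate_shapes(lp$peaks[1, ], lp$chrom, lp$feature[1, ],
                               gate_cfg)
  r_unbiased <- correlate_shapes(lp$peaks[1, ], lp$chrom, lp$feature[1, ],
                                 correlation_config(rt_bias = 0,
                                                    rt_window = 30))
  expect_gt(r_biased$pearson_r, 0.999)
  expect_gt(r_biased$pearson_r, r_unbiased$pearson_r)
})

test_that("the Pearson implementation agrees with the direct formula to 1e-12", {
  for (seed in 1:100) {
    v <- withr::with_seed(seed, list(x = rnorm(20), y = rnorm(20)))
    expect_equal(cor(v$x, v$y), pearson_direct(v$x, v$y), tolerance = 1e-12)
  }
  # invariance under positive affine transforms of either input
  v <- withr::with_seed(7, list(x = runif(30), y = runif(30)))
  r0 <- pearson_direct(v$x, v$y)
  expect_equal(pearson_direct(3 * v$x + 11, v$y), r0, tolerance = 1e-12)
  expect_equal(pearson_direct(v$x, 0.2 * v$y - 4), r0, tolerance = 1e-12)
})

test_that("ranking keeps strictly-above-threshold results with the tie-breaks", {
  cfg <- correlation_config(r_threshold = 0.8)
  res <- data.frame(
    peak_id = 1L, activity_peak_apex_rt = 2, activity_auc = 1,
    feature_id = c("A", "B", "C"), mz = c(300, 400, 500),
    feature_apex_rt = 2, rt_offset_s = c(1, 2, 3),
    pearson_r = c(0.95, 0.85, 0.75), n_points = 20L)
  rk <- rank_features(res, cfg)
  expect_equal(nrow(rk), 2L)
  expect_equal(rk$feature_id, c("A", "B"))
  expect_equal(rk$rank, 1:2)

  # exactly at the threshold: dropped (strictly above)
  at <- res; at$pearson_r <- c(0.8, 0.8, 0.8)
  expect_equal(nrow(rank_features(at, cfg)), 0L)

  expect_equal(nrow(rank_features(res[0, ], cfg)), 0L)

  # tie on r: smaller |offset| first, then lower m/z
  tie <- data.frame(
    peak_id = 1L, activity_peak_apex_rt = 2, activity_auc = 1,
    feature_id = c("X", "Y", "Z"), mz = c(500, 300, 200),
    feature_apex_rt = 2, rt_offset_s = c(2, 5, 5),
    pearson_r = 0.9, n_points = 20L)
  rk2 <- rank_features(tie, cfg)
  expect_equal(rk2$feature_id, c("X", "Z", "Y"))
})

test_that("result export round-trips through CSV", {
  cfg <- correlation_config()
  lp <- linked_pair(noise_sd = 0.02, seed = 3)
  res <- correlate_features(lp$peaks, lp$chrom, lp$feature, cfg)
  expect_equal(nrow(res), 1L)
  d <- withr::local_tempdir()
  p <- file.path(d, "ranked.csv")
  export_results(res, p)
  back <- read_results(p)
  expect_equal(back$feature_id, res$feature_id)
  expect_equal(back$pearson_r, res$pearson_r)
  expect_equal(back$rank, res$rank)

  export_results(res[0, ], p)
  expect_equal(nrow(read_results(p)), 0L)
})

test_that("the MS2 filter keeps exactly the matching precursors", {
  # planted compound with MS2 scans plus decoys with their own MS2
  run <- generate_lcms_run(
    list(planted_compound(402.18, 0.5, 0.05, 1e6)),
    rt_span = c(0, 1), scan_rate = 2, n_decoys = 2, seed = 21,
    ms2_per_compound = 3)
  feats <- find_features(run$series)
  target <- feats[abs(feats$mz - 402.18) < 0.01, , drop = FALSE]
  ranked <- data.frame(feature_id = target$feature_id, pearson_r = 0.99,
                       rank = 1L)
  cfg <- correlation_config()
  d <- withr::local_tempdir()
  p <- file.path(d, "f.mzML")
  kept <- filter_ms2_for_networking(run$series, ranked, feats, cfg, p)
  expect_equal(length(kept), 3L)   # 3 of the 9 MS2 scans
  back <- read_mzml(p)
  expect_equal(length(back), 3L)
  # every exported scan satisfies both predicates
  for (s in back$scans) {
    expect_equal(s$ms_level, 2L)
    expect_lt(abs(s$precursor_mz - target$mz), cfg$mz_tol_ms2)
    expect_true(s$rt >= target$start_rt && s$rt <= target$end_rt)
  }

  # nothing retained -> structurally valid empty mzML
  kept0 <- filter_ms2_for_networking(run$series, ranked[0, ], feats, cfg, p)
  expect_equal(length(kept0), 0L)
  expect_equal(length(read_mzml(p)), 0L)

  # retained feature without MS2 in range -> empty output with warning
  fake <- feats[1, ]; fake$feature_id <- "F999"; fake$mz <- 777.7
  fake$start_rt <- 0.9; fake$end_rt <- 0.95
  feats2 <- rbind(feats, fake)
  expect_warning(
    filter_ms2_for_networking(run$series,
                              data.frame(feature_id = "F999"), feats2, cfg, p),
    "no MS2")
})
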
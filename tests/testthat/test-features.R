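make_run <- function(compounds, ..., seed = 1) {
  generate_lcms_run(compounds, ..., seed = seed)
}

test_that("XIC extraction sums matching centroids per MS1 scan", {
  run <- make_run(list(planted_compound(350.2, 0.5, 0.06, 8e5)),
                  rt_span = c(0, 1), scan_rate = 2)
  # absent m/z: all-zero XIC with one row per MS1 scan
  x0 <- extract_xic(run$series, 999.9, 10)
  expect_equal(nrow(x0), 121L)
  expect_true(all(x0$intensity == 0))
  # planted feature: apex within one scan of truth
  x1 <- extract_xic(run$series, 350.2, 10)
  expect_lt(abs(x1$rt[which.max(x1$intensity)] - 0.5), 1 / 120 + 1e-12)

  # isobaric peaks within tolerance sum: brute-force over one scan
  s <- spectrum_series(list(list(
    rt = 0.1, ms_level = 1L, precursor_mz = NA_real_,
    mz = c(400.000, 400.002, 410), intensity = c(5, 7, 100))))
  x2 <- extract_xic(s, 400.001, 10)   # 10 ppm of 400 = 0.004
  expect_equal(x2$intensity, 12)
})

test_that("XIC completeness: per-compound XICs partition the total ion current", {
  run <- make_run(list(planted_compound(350.2, 0.5, 0.05, 8e5),
                       planted_compound(520.7, 0.9, 0.04, 5e5)),
                  rt_span = c(0, 1.4), scan_rate = 2, n_decoys = 8,
                  noise = 0.02, seed = 9)
  mzs <- vapply(run$truth$compounds, function(c) c$mz, numeric(1))
  total_xic <- Reduce(`+`, lapply(mzs, function(m)
    extract_xic(run$series, m, 10)$intensity))
  tic <- total_ion_current(run$series)$tic
  expect_equal(sum(total_xic), sum(tic), tolerance = 1e-6)
})

test_that("mass-trace chaining isolates m/z channels", {
  run <- make_run(list(planted_compound(350.2, 0.5, 0.05, 8e5)),
                  rt_span = c(0, 1), scan_rate = 2)
  tr <- build_mass_traces(run$series, ppm_tol = 10, min_trace_length = 5)
  expect_equal(length(tr), 1L)
  expect_lt(abs(attr(tr[[1]], "mean_mz") - 350.2) / 350.2 * 1e6, 10)

  # min_trace_length beyond the scan count: nothing survives
  expect_equal(length(build_mass_traces(run$series, 10,
                                        min_trace_length = 1000)), 0L)

  # two features 50 ppm apart resolve into distinct traces at 10 ppm
  mz0 <- 500
  run2 <- make_run(list(planted_compound(mz0, 0.4, 0.05, 6e5),
                        planted_compound(mz0 * (1 + 50e-6), 0.45, 0.05, 6e5)),
                   rt_span = c(0, 0.9), scan_rate = 2)
  tr2 <- build_mass_traces(run2$series, ppm_tol = 10, min_trace_length = 5)
  expect_equal(length(tr2), 2L)
})

test_that("elution-peak detection handles unimodal, bimodal and boundary apexes", {
  run <- make_run(list(planted_compound(350.2, 0.5, 0.05, 8e5)),
                  rt_span = c(0, 1), scan_rate = 2)
  tr <- build_mass_traces(run$series, 10, 5)[[1]]
  f <- detect_feature_peaks(tr)
  expect_equal(nrow(f), 1L)
  expect_lt(abs(f$apex_rt - 0.5), 1 / 120 + 1e-12)
  expect_equal(f$apex_intensity, max(f$profile[[1]]$intensity))

  # bimodal trace: two Gaussians, valley well below both apexes
  rt <- seq(0, 1, by = 1 / 120)
  y <- 1e5 * (exp(-(rt - 0.3)^2 / (2 * 0.04^2)) +
                0.8 * exp(-(rt - 0.7)^2 / (2 * 0.04^2)))
  bim <- structure(data.frame(rt = rt, mz = 400, intensity = y),
                   class = c("mass_trace", "data.frame"), mean_mz = 400)
  f2 <- detect_feature_peaks(bim)
  expect_equal(nrow(f2), 2L)
  expect_equal(f2$apex_rt, c(0.3, 0.7), tolerance = 1 / 120)

  # monotonically increasing trace: apex at the last point
  mono <- structure(data.frame(rt = rt[1:50], mz = 400,
                               intensity = seq(1e3, 1e5, length.out = 50)),
                    class = c("mass_trace", "data.frame"), mean_mz = 400)
  f3 <- detect_feature_peaks(mono)
  expect_equal(nrow(f3), 1L)
  expect_equal(f3$apex_rt, rt[50])
})

test_that("planted features are recovered one-to-one over a seed sweep", {
  for (seed in 1:20) {
    mzs <- withr::with_seed(seed, sort(runif(3, 200, 900)))
    # enforce pairwise m/z separation > 3 * ppm_tol
    mzs <- mzs * c(1, 1.001, 1.002); mzs <- mzs + c(0, 5, 10)
    apexes <- withr::with_seed(seed + 7, runif(3, 0.3, 1.2))
    cps <- lapply(1:3, function(k)
      planted_compound(mzs[k], apexes[k], 0.05, 7e5))
    run <- make_run(cps, rt_span = c(0, 1.5), scan_rate = 2,
                    noise = 0.05, seed = seed)  # SNR >> 10
    f <- find_features(run$series, ppm_tol = 10, min_trace_length = 5)
    expect_equal(nrow(f), 3L)
    for (k in 1:3) {
      hit <- which(abs(f$mz - mzs[k]) / mzs[k] * 1e6 <= 10)
      expect_equal(length(hit), 1L)
      expect_lt(abs(f$apex_rt[hit] - apexes[k]), 3 / 120)
    }
  }
})

test_that("the detector is idempotent on a feature's own profile", {
  run <- make_run(list(planted_compound(350.2, 0.5, 0.05, 8e5)),
                  rt_span = c(0, 1), scan_rate = 2)
  f <- find_features(run$series)
  prof <- f$profile[[1]]
  tr <- structure(data.frame(rt = prof$rt, mz = f$mz[1],
                             intensity = prof$intensity),
                  class = c("mass_trace", "data.frame"), mean_mz = f$mz[1])
  f2 <- detect_feature_peaks(tr)
  expect_equal(nrow(f2), 1L)
  expect_equal(f2$apex_rt, f$apex_rt[1])
})

test_that("feature tables validate, round-trip and refill profiles from XICs", {
  d <- withr::local_tempdir()
  run <- make_run(list(planted_compound(350.2, 0.5, 0.05, 8e5)),
                  rt_span = c(0, 1), scan_rate = 2)
  f <- find_features(run$series)
  p <- file.path(d, "features.csv")
  write_feature_table(f, p)
  f2 <- read_feature_table(p)
  expect_equal(nrow(f2), nrow(f))
  expect_equal(f2$mz, f$mz)
  expect_null(f2$profile[[1]])

  f3 <- fill_feature_profiles(f2, run$series, ppm_tol = 10)
  # refilled profile equals the XIC restricted to the (round-tripped) bounds
  xic <- extract_xic(run$series, f2$mz[1], 10)
  sel <- xic$rt >= f2$start_rt[1] & xic$rt <= f2$end_rt[1]
  expect_equal(f3$profile[[1]]$intensity, xic$intensity[sel])

  # validation: bad bounds name the row, missing columns are named
  bad <- data.frame(feature_id = "X1", mz = 100, apex_rt = 1,
                    start_rt = 2, end_rt = 0.5, apex_intensity = 10)
  pb <- file.path(d, "bad.csv"); write.csv(bad, pb, row.names = FALSE)
  expect_error(read_feature_table(pb), "row.* 1")
  nohdr <- file.path(d, "nohdr.csv")
  write.csv(bad[, -2], nohdr, row.names = FALSE)
  expect_error(read_feature_table(nohdr), "mz")
})
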
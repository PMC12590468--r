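test_that("image loading handles inversion and round-trips through PNG", {
  m <- matrix(c(0, 2, 1, 3) / 3, 2, 2)  # [[0,1],[2,3]]/3 row-major
  expect_equal(as_intensity_image(m)$pixels, m)
  inv <- as_intensity_image(m, invert = TRUE)
  expect_equal(inv$pixels, max(m) - m)

  # PNG round-trip of a known blob: brightest pixel at planted center
  g <- blob_image(2, 2, pitch = 40, spot_radius = 8,
                  activities = c(4, 0, 0, 0), noise_sd = 0)
  path <- withr::local_tempfile(fileext = ".png")
  write_luminescence_image(g$image, path)
  img <- load_luminescence_image(path)
  peak <- which(img$pixels == max(img$pixels), arr.ind = TRUE)[1, ]
  ctr <- g$truth$centers[1, ]
  expect_lt(abs(peak["col"] - ctr$x), 1.01)
  expect_lt(abs(peak["row"] - ctr$y), 1.01)

  expect_error(load_luminescence_image(file.path(tempdir(), "nope.png")),
               class = "biospot_io_error")
  expect_error(as_intensity_image(matrix(numeric(0), 0, 0)),
               class = "biospot_validation_error")
})

test_that("candidate detection finds planted blobs and ignores blanks", {
  blank <- as_intensity_image(matrix(0.3, 60, 60))
  expect_equal(nrow(detect_candidate_spots(blank, c(3, 8))), 0L)

  g <- blob_image(3, 4, activities = rep(3, 12), noise_sd = 0)
  cand <- detect_candidate_spots(g$image, c(2.5, 8))
  expect_equal(nrow(cand), 12L)
  # each candidate within 1 px of a planted center
  tr <- g$truth$centers
  d <- vapply(seq_len(nrow(cand)), function(k)
    min(sqrt((tr$x - cand$x[k])^2 + (tr$y - cand$y[k])^2)), numeric(1))
  expect_lt(max(d), 1)

  # half the spots dark: the active ones are still found
  act <- rep(c(3, 0), 6)
  g2 <- blob_image(3, 4, activities = act, noise_sd = 0)
  cand2 <- detect_candidate_spots(g2$image, c(2.5, 8))
  expect_gte(nrow(cand2), 6L)
  on <- g2$truth$centers[act > 0, ]
  d2 <- vapply(which(act > 0), function(k) {
    min(sqrt((cand2$x - g2$truth$centers$x[k])^2 +
               (cand2$y - g2$truth$centers$y[k])^2))
  }, numeric(1))
  expect_lt(max(d2), 1)
})

test_that("grid fit recovers exact and rotated lattices, rejects degenerate input", {
  # exact axis-aligned lattice, pitch 20
  cand <- expand.grid(x = 20 * (0:3) + 30, y = 20 * (0:2) + 30)
  layout <- pad_layout(3, 4, pitch = 20, spot_radius = 5)
  g <- fit_spot_grid(cand, layout)
  expect_equal(unname(g$row_step), c(0, 20), tolerance = 1e-8)
  expect_equal(unname(g$col_step), c(20, 0), tolerance = 1e-8)
  expect_lt(g$rms_residual, 1e-8)

  expect_error(fit_spot_grid(data.frame(x = c(1, 2), y = c(1, 2)), layout),
               class = "biospot_validation_error")
  expect_error(
    fit_spot_grid(data.frame(x = 1:5, y = 2 * (1:5) + 3), layout),
    "collinear")

  # corner hints alone define a usable grid
  gh <- fit_spot_grid(empty_candidates <- data.frame(x = numeric(0),
                                                     y = numeric(0)),
                      layout, corner_hints = rbind(c(30, 30), c(90, 30),
                                                   c(30, 70)))
  ctr <- predict_centers(gh, 2, 3)
  expect_equal(unname(ctr[1, ]), c(90, 70), tolerance = 1e-8)
})

test_that("grid recovery stays within 1 px under rotation and dark spots", {
  layout <- pad_layout(10, 10, pitch = 20, spot_radius = 5)
  for (seed in 1:6) {
    act <- withr::with_seed(seed, ifelse(runif(100) < 0.4, 3, 0))
    act[c(1, 100)] <- 3   # keep at least the extreme fractions measurable
    rot <- withr::with_seed(seed + 100, runif(1, -5, 5))
    g <- generate_upad_image(layout, act, rotation_deg = rot,
                             noise_sd = 0.004, seed = seed)
    cand <- detect_candidate_spots(g$image, c(2.5, 8))
    grid <- fit_spot_grid(cand, layout, image_dim = dim(g$image$pixels))
    ord <- serpentine_order(10, 10)
    pred <- predict_centers(grid, ord$grid_row, ord$grid_col)
    err <- sqrt((pred[, "x"] - g$truth$centers$x)^2 +
                  (pred[, "y"] - g$truth$centers$y)^2)
    expect_lt(max(err), 1)
  }
})

test_that("serpentine enumeration follows the boustrophedon convention", {
  layout <- pad_layout(2, 3, pitch = 20, spot_radius = 5)
  g <- fit_spot_grid(NULL, layout,
                     corner_hints = rbind(c(10, 10), c(50, 10), c(10, 30)))
  tab <- enumerate_spots(g, layout)
  expect_equal(tab$label, c("A1", "A2", "A3", "B3", "B2", "B1"))
  expect_equal(tab$serpentine_index, 0:5)
  # brute-force oracle: walk the lattice row by row, alternating direction
  walk <- list()
  for (r in 0:1) {
    cols <- if (r %% 2 == 0) 0:2 else 2:0
    for (c in cols) walk[[length(walk) + 1L]] <- c(r, c)
  }
  expect_equal(tab$grid_row, vapply(walk, `[`, numeric(1), 1))
  expect_equal(tab$grid_col, vapply(walk, `[`, numeric(1), 2))
  expect_equal(tab$serpentine_index[tab$label == "B1"], 5L)

  off <- enumerate_spots(g, layout, index_offset = 100L)
  expect_equal(off$serpentine_index[1], 100L)
})

test_that("serpentine indexing is a bijection for arbitrary layouts", {
  for (dims in list(c(1, 1), c(1, 7), c(4, 1), c(5, 8), c(27, 3))) {
    ord <- serpentine_order(dims[1], dims[2])
    expect_equal(sort(ord$serpentine_index), 0:(prod(dims) - 1))
    expect_equal(anyDuplicated(ord[c("grid_row", "grid_col")]), 0L)
    # index -> (row, col) -> index is the identity
    back <- vapply(seq_len(nrow(ord)), function(k) {
      r <- ord$grid_row[k]
      pos <- if (r %% 2 == 0) ord$grid_col[k] else dims[2] - 1 - ord$grid_col[k]
      r * dims[2] + pos
    }, numeric(1))
    expect_equal(back, ord$serpentine_index)
  }
})

test_that("spot intensity is the disk mean, clipping and monotone in amplitude", {
  const <- as_intensity_image(matrix(7, 40, 40))
  expect_equal(measure_spot_intensity(const, c(20, 20), 6), 7)

  # step edge through the disk center: brute-force pixel-count oracle
  m <- matrix(0, 40, 40); m[, 21:40] <- 10
  img <- as_intensity_image(m)
  got <- measure_spot_intensity(img, c(20.5, 20), 8)
  px <- expand.grid(i = 1:40, j = 1:40)
  sel <- (px$j - 20.5)^2 + (px$i - 20)^2 <= 64
  expect_equal(got, mean(m[cbind(px$i[sel], px$j[sel])]))
  expect_equal(got, 5, tolerance = 0.05)

  # blob mean strictly between background and background + amplitude
  g <- blob_image(1, 1, pitch = 40, spot_radius = 6, activities = 2,
                  noise_sd = 0, background = 0.05)
  v <- measure_spot_intensity(g$image, unlist(g$truth$centers[1, c("x", "y")]),
                              4.8)
  expect_gt(v, 0.05); expect_lt(v, 0.05 + 2 * g$truth$amp_per_activity)

  # monotonicity in planted amplitude
  amps <- c(0.5, 1, 2, 4, 8)
  means <- vapply(amps, function(a) {
    gg <- blob_image(1, 1, pitch = 40, spot_radius = 6, activities = a,
                     noise_sd = 0)
    measure_spot_intensity(gg$image,
                           unlist(gg$truth$centers[1, c("x", "y")]), 4.8)
  }, numeric(1))
  expect_true(all(diff(means) > 0))

  expect_warning(measure_spot_intensity(const, c(2, 2), 6), "clipped")
  expect_error(measure_spot_intensity(const, c(-50, -50), 6),
               class = "biospot_validation_error")
})

test_that("halo measurement recovers planted annuli and reports absence", {
  flat <- as_intensity_image(matrix(0.05, 60, 60))
  expect_true(is.na(measure_halo(flat, c(30, 30), 6, 25, 0.05, 0.002)))

  # planted annulus between 8 and 14 px -> outer radius 14 +- 1
  layout <- pad_layout(1, 1, pitch = 60, spot_radius = 5)
  halos <- data.frame(index = 0, r_inner = 8, r_outer = 14, amplitude = 0.1)
  g <- generate_upad_image(layout, activities = 2, halos = halos,
                           noise_sd = 0.003, margin = 30, seed = 42)
  ctr <- unlist(g$truth$centers[1, c("x", "y")])
  bg <- estimate_background(g$image, cbind(ctr[1], ctr[2]), 25)
  hr <- measure_halo(g$image, ctr, 6, 25, bg$background, bg$scale)
  expect_lt(abs(hr - 14), 1.01)

  # bright disk only, no annulus -> absent
  g2 <- generate_upad_image(layout, activities = 4, noise_sd = 0.003,
                            margin = 30, seed = 43)
  bg2 <- estimate_background(g2$image, cbind(ctr[1], ctr[2]), 25)
  expect_true(is.na(measure_halo(g2$image, ctr, 6, 25, bg2$background,
                                 bg2$scale)))
})

test_that("halo radius recovery holds over a seed sweep", {
  layout <- pad_layout(1, 1, pitch = 70, spot_radius = 5)
  for (seed in 1:20) {
    r_out <- withr::with_seed(seed, sample(11:18, 1))
    halos <- data.frame(index = 0, r_inner = r_out - 4, r_outer = r_out,
                        amplitude = 0.1)
    g <- generate_upad_image(layout, activities = 2, halos = halos,
                             noise_sd = 0.004, margin = 35, seed = seed)
    ctr <- unlist(g$truth$centers[1, c("x", "y")])
    bg <- estimate_background(g$image, cbind(ctr[1], ctr[2]), 30)
    hr <- measure_halo(g$image, ctr, 6, 30, bg$background, bg$scale)
    expect_lt(abs(hr - r_out), 1.01)
  }
})

test_that("activity combination follows the commensuration rule", {
  expect_equal(compute_activity(4, NA, 20, 5), 4)
  expect_equal(compute_activity(4, 12, 20, 5, halo_weight = 0), 4)
  # mean 4, halo radius = pitch/2, weight 1, scale 4 -> 4 + 1 * 1 * 4 = 8
  expect_equal(compute_activity(4, 10, 20, 4), 8)
})

test_that("median normalization yields the unit-median invariant", {
  tab <- as_spot_table_for_test(c(2, 4, 6))
  norm <- normalize_by_median(tab)
  expect_equal(norm$norm_activity, c(0.5, 1.0, 1.5))

  same <- normalize_by_median(as_spot_table_for_test(rep(3.3, 5)))
  expect_equal(same$norm_activity, rep(1, 5))

  for (seed in 1:5) {
    raw <- withr::with_seed(seed, runif(2 * sample(3:20, 1) + 1, 0.1, 9))
    norm <- normalize_by_median(as_spot_table_for_test(raw))
    expect_identical(median(norm$norm_activity), 1)  # odd count: exact
  }
  expect_error(normalize_by_median(as_spot_table_for_test(c(0, 0, 0))),
               class = "biospot_validation_error")
})

test_that("merging spot tables enforces contiguous disjoint index ranges", {
  t1 <- as_spot_table_for_test(runif(5), offset = 0)
  t2 <- as_spot_table_for_test(runif(5), offset = 5)
  m <- merge_spot_tables(list(t1, t2))
  expect_equal(m$serpentine_index, 0:9)
  expect_identical(merge_spot_tables(list(t1)), t1)
  overlap <- as_spot_table_for_test(runif(5), offset = 3)
  expect_error(merge_spot_tables(list(t1, overlap)), "overlap")
  gap <- as_spot_table_for_test(runif(5), offset = 7)
  expect_error(merge_spot_tables(list(t1, gap)), "gap")
})

test_that("full image densitometry reproduces planted activity patterns", {
  layout <- pad_layout(5, 5, pitch = 20, spot_radius = 5)
  act <- rep(1, 25); act[12] <- 5; act[13] <- 3
  g <- generate_upad_image(layout, act, noise_sd = 0.004, seed = 11)
  tab <- analyze_upad_image(g$image, layout, halo_weight = 0)
  expect_equal(nrow(tab), 25L)
  expect_equal(which.max(tab$norm_activity) - 1L, 11L)  # serpentine index 11
  expect_equal(order(tab$norm_activity, decreasing = TRUE)[1:2] - 1L,
               c(11L, 12L))
  # normalized baseline sits near 1
  expect_lt(abs(median(tab$norm_activity) - 1), 1e-9)
})
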
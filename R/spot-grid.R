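#' Detect candidate spot centers in a luminescence image
#'
#' Finds bright, roughly circular blobs by thresholding above the image
#' background and extracting connected components whose area is compatible
#' with `radius_range`.  Inactive fractions emit no light, so dark spots are
#' expected to be missed here; [fit_spot_grid()] imputes their centers from
#' the lattice model.
#'
#' @param img An `intensity_image` (or matrix).
#' @param radius_range Numeric pair `(min, max)` of plausible spot radii in
#'   pixels.
#' @param min_contrast Fraction of the background-to-bright dynamic range a
#'   blob must exceed (default 0.25).  The threshold is
#'   `background + min_contrast * (q - background)` with the background
#'   taken as the image median and `q` the 99.5% intensity quantile (robust
#'   to a single very bright spot), floored at four robust noise SDs above
#'   background so noise speckle never segments.
#' @return A data.frame with `x`, `y` (intensity-weighted centroids, pixel
#'   coordinates where pixel `[i, j]` has center `x = j`, `y = i`),
#'   `radius_px` (equivalent-disk radius) and `peak_intensity`; possibly
#'   zero rows.
#' @export
detect_candidate_spots <- function(img, radius_range, min_contrast = 0.25) {
  img <- as_intensity_image(img)
  px <- img$pixels
  if (length(radius_range) != 2L || any(radius_range <= 0) ||
      radius_range[1] > radius_range[2])
    abort_validation("radius_range must be an increasing positive pair")
  if (2 * radius_range[2] > max(dim(px)))
    abort_validation("radius_range exceeds image dimensions")
  bg <- median(px)
  noise <- 1.4826 * mad(px, constant = 1)
  q_hi <- stats::quantile(px, 0.995, names = FALSE)
  thr <- bg + max(min_contrast * (q_hi - bg), 4 * noise)
  fg <- px > thr
  if (!any(fg)) return(empty_candidates())
  lab <- label_components(fg)
  a_min <- pi * radius_range[1]^2 / 2
  a_max <- pi * radius_range[2]^2 * 2
  ids <- which(tabulate(lab$labels) >= a_min & tabulate(lab$labels) <= a_max)
  if (!length(ids)) return(empty_candidates())
  out <- lapply(ids, function(id) {
    sel <- lab$labels == id
    i <- lab$row[sel]; j <- lab$col[sel]
    w <- px[cbind(i, j)] - bg
    w <- pmax(w, 1e-12)
    data.frame(x = sum(j * w) / sum(w), y = sum(i * w) / sum(w),
               radius_px = sqrt(length(i) / pi),
               peak_intensity = max(px[cbind(i, j)]))
  })
  out <- do.call(rbind, out)
  out[order(out$y, out$x), , drop = FALSE]
}

empty_candidates <- function() {
  data.frame(x = numeric(0), y = numeric(0), radius_px = numeric(0),
             peak_intensity = numeric(0))
}

# 4-connected component labelling of a logical matrix; plain BFS, adequate
# for uPAD-sized images (tens of blobs on a few hundred px squared).
label_components <- function(fg) {
  nr <- nrow(fg); nc <- ncol(fg)
  idx <- which(fg)
  labels <- integer(length(idx))
  pos <- integer(nr * nc); pos[idx] <- seq_along(idx)  # linear idx -> compact idx
  cur <- 0L
  for (s in seq_along(idx)) {
    if (labels[s] != 0L) next
    cur <- cur + 1L
    queue <- idx[s]; labels[s] <- cur
    qh <- 1L
    while (qh <= length(queue)) {
      p <- queue[[qh]]; qh <- qh + 1L
      i <- (p - 1L) %% nr + 1L; j <- (p - 1L) %/% nr + 1L
      nb <- c(if (i > 1L) p - 1L, if (i < nr) p + 1L,
              if (j > 1L) p - nr, if (j < nc) p + nr)
      ok <- pos[nb] != 0L
      ok[ok] <- labels[pos[nb[ok]]] == 0L
      nb <- nb[ok]
      if (length(nb)) { labels[pos[nb]] <- cur; queue <- c(queue, nb) }
    }
  }
  lin <- idx
  list(labels = labels, row = (lin - 1L) %% nr + 1L, col = (lin - 1L) %/% nr + 1L)
}

#' Fit a lattice model to detected spot candidates
#'
#' Least-squares fit of origin plus two basis vectors (row step and column
#' step, jointly encoding pitch and rotation) to the candidate centers, so
#' that every lattice node -- including spots that emitted no light --
#' obtains a predicted center.  Candidates are assigned to nodes from a
#' rotation/pitch estimate (nearest-neighbour displacement angles folded to
#' one quadrant), then assignment and fit are iterated to convergence.
#'
#' @param candidates Data.frame with `x`, `y` columns as returned by
#'   [detect_candidate_spots()].
#' @param layout A [pad_layout()].
#' @param corner_hints Optional 2--4 row matrix (or list) of pixel
#'   coordinates in the order top-left, top-right, bottom-left
#'   (, bottom-right), used when too few blobs are visible for a blind fit.
#' @param image_dim Optional `c(n_pixel_rows, n_pixel_cols)` of the source
#'   image.  When whole border rows or columns of the lattice are dark,
#'   candidate indices alone cannot anchor the lattice window; the anchor
#'   is then chosen so the full lattice sits inside the image with maximal
#'   border margin.
#' @return A `grid_model`: `origin` (x, y of node row 0, col 0), `row_step`,
#'   `col_step` (pixel vectors), `rms_residual` (px over assigned
#'   candidates), `n_assigned`.
#' @export
fit_spot_grid <- function(candidates, layout, corner_hints = NULL,
                          image_dim = NULL) {
  stopifnot(inherits(layout, "pad_layout"))
  if (!is.null(corner_hints))
    return(grid_from_corners(corner_hints, layout, candidates))
  if (is.null(candidates) || nrow(candidates) < 3L)
    abort_validation(
      "need >= 3 spot candidates for a blind grid fit (got %d); supply corner_hints",
      if (is.null(candidates)) 0L else nrow(candidates))
  P <- cbind(candidates$x, candidates$y)
  if (collinear(P))
    abort_validation("spot candidates are collinear; supply corner_hints")

  est <- estimate_rotation_pitch(P, layout$pitch)
  # derotate, bin to integer indices
  R <- rot2(-est$theta)
  Q <- P %*% t(R)
  r0 <- round((Q[, 2] - min(Q[, 2])) / est$pitch)
  c0 <- round((Q[, 1] - min(Q[, 1])) / est$pitch)
  g <- fit_lattice_ls(P, r0, c0)
  for (it in 1:4) {
    rc <- assign_nodes(P, g, layout)
    g2 <- fit_lattice_ls(P[rc$keep, , drop = FALSE],
                         rc$r[rc$keep], rc$c[rc$keep])
    if (max(abs(unlist(g2[c("origin", "row_step", "col_step")]) -
                unlist(g[c("origin", "row_step", "col_step")]))) < 1e-9) {
      g <- g2; break
    }
    g <- g2
  }
  g <- anchor_lattice(g, rc, layout, image_dim)
  g$n_assigned <- sum(rc$keep)
  structure(g, class = "grid_model")
}

# Shift the lattice window (relabel indices by a constant) so the full
# n_rows x n_cols lattice sits inside the image with maximal border
# margin.  Needed when whole border rows/columns are dark: candidates then
# under-determine where the window starts.
anchor_lattice <- function(g, rc, layout, image_dim) {
  if (is.null(image_dim)) return(g)
  r <- rc$r[rc$keep]; c <- rc$c[rc$keep]
  drs <- seq.int(-min(r), layout$n_rows - 1L - max(r))
  dcs <- seq.int(-min(c), layout$n_cols - 1L - max(c))
  if (length(drs) == 1L && length(dcs) == 1L && drs == 0L && dcs == 0L)
    return(g)
  corners <- rbind(c(0, 0), c(0, layout$n_cols - 1L),
                   c(layout$n_rows - 1L, 0),
                   c(layout$n_rows - 1L, layout$n_cols - 1L))
  best <- c(0L, 0L); best_m <- -Inf
  for (dr in drs) for (dc in dcs) {
    o <- g$origin - dr * g$row_step - dc * g$col_step
    x <- o["x"] + corners[, 1] * g$row_step["x"] + corners[, 2] * g$col_step["x"]
    y <- o["y"] + corners[, 1] * g$row_step["y"] + corners[, 2] * g$col_step["y"]
    m <- min(x - 1, image_dim[2] - x, y - 1, image_dim[1] - y)
    if (m > best_m) { best_m <- m; best <- c(dr, dc) }
  }
  g$origin <- g$origin - best[1] * g$row_step - best[2] * g$col_step
  g
}

collinear <- function(P, tol = 1e-6) {
  if (nrow(P) < 3L) return(TRUE)
  C <- sweep(P, 2, colMeans(P))
  sv <- svd(C, nu = 0, nv = 0)$d
  sv[2] <= tol * max(sv[1], 1)
}

rot2 <- function(theta) {
  matrix(c(cos(theta), -sin(theta), sin(theta), cos(theta)), 2, 2, byrow = TRUE)
}

# Rotation estimated from near-pitch pairwise displacements, folded mod 90
# degrees; pitch from their median length.
estimate_rotation_pitch <- function(P, pitch_hint) {
  n <- nrow(P)
  D <- as.matrix(dist(P))
  diag(D) <- Inf
  nn <- apply(D, 1, min)
  p_hat <- median(nn)
  if (!is.finite(pitch_hint) || pitch_hint <= 0) pitch_hint <- p_hat
  # prefer the layout pitch when the nearest-neighbour estimate disagrees
  # wildly (sparse active spots leave lattice gaps)
  if (abs(p_hat - pitch_hint) / pitch_hint > 0.25) p_hat <- pitch_hint
  keep <- which(D < 1.35 * p_hat & D > 0.65 * p_hat, arr.ind = TRUE)
  if (nrow(keep) == 0) return(list(theta = 0, pitch = p_hat))
  dx <- P[keep[, 2], 1] - P[keep[, 1], 1]
  dy <- P[keep[, 2], 2] - P[keep[, 1], 2]
  ang <- atan2(dy, dx) %% (pi / 2)
  ang[ang > pi / 4] <- ang[ang > pi / 4] - pi / 2
  theta <- median(ang)
  len <- median(sqrt(dx^2 + dy^2))
  list(theta = theta, pitch = len)
}

fit_lattice_ls <- function(P, r, c) {
  X <- cbind(1, r, c)
  bx <- qr.coef(qr(X), P[, 1])
  by <- qr.coef(qr(X), P[, 2])
  bx[is.na(bx)] <- 0; by[is.na(by)] <- 0
  pred <- X %*% cbind(bx, by)
  rms <- sqrt(mean(rowSums((P - pred)^2)))
  list(origin = c(x = unname(bx[1]), y = unname(by[1])),
       row_step = c(x = unname(bx[2]), y = unname(by[2])),
       col_step = c(x = unname(bx[3]), y = unname(by[3])),
       rms_residual = rms)
}

# Solve [r, c] for each point from the current basis, shift into the layout
# window, and drop duplicate/out-of-range assignments (nearest wins).
assign_nodes <- function(P, g, layout) {
  B <- cbind(g$row_step, g$col_step)      # columns: d(center)/dr, d(center)/dc
  rc <- t(solve(B, t(sweep(P, 2, g$origin))))
  r <- round(rc[, 1]); c <- round(rc[, 2])
  r <- r - min(r); c <- c - min(c)
  # clamp the window so indices fit the layout (spurious far-out blobs drop)
  keep <- r >= 0 & r < layout$n_rows & c >= 0 & c < layout$n_cols
  pred <- sweep(cbind(r, c) %*% t(B), 2, g$origin, "+")
  d2 <- rowSums((P - pred)^2)
  key <- paste(r, c)
  for (k in unique(key[keep])) {
    sel <- which(key == k & keep)
    if (length(sel) > 1L) keep[sel[-which.min(d2[sel])]] <- FALSE
  }
  list(r = r, c = c, keep = keep)
}

grid_from_corners <- function(corner_hints, layout, candidates = NULL) {
  H <- do.call(rbind, lapply(
    if (is.matrix(corner_hints)) split(corner_hints, row(corner_hints)[, 1])
    else corner_hints, as.numeric))
  if (ncol(H) != 2L || nrow(H) < 2L || nrow(H) > 4L)
    abort_validation("corner_hints must be 2-4 (x, y) coordinates")
  nr <- layout$n_rows; nc <- layout$n_cols
  tl <- H[1, ]; tr <- H[2, ]
  col_step <- if (nc > 1L) (tr - tl) / (nc - 1L) else c(layout$pitch, 0)
  if (nrow(H) >= 3L) {
    bl <- H[3, ]
    row_step <- if (nr > 1L) (bl - tl) / (nr - 1L) else rot90(col_step)
  } else {
    row_step <- rot90(col_step)  # perpendicular, same pitch, pointing down
  }
  g <- list(origin = c(x = tl[1], y = tl[2]),
            row_step = c(x = row_step[1], y = row_step[2]),
            col_step = c(x = col_step[1], y = col_step[2]),
            rms_residual = NA_real_, n_assigned = 0L)
  g <- structure(g, class = "grid_model")
  if (!is.null(candidates) && nrow(candidates) >= 3L) {
    # refine with the candidates actually seen
    P <- cbind(candidates$x, candidates$y)
    rc <- assign_nodes(P, g, layout)
    if (sum(rc$keep) >= 3L && !collinear(P[rc$keep, , drop = FALSE])) {
      g2 <- fit_lattice_ls(P[rc$keep, , drop = FALSE],
                           rc$r[rc$keep], rc$c[rc$keep])
      g2$n_assigned <- sum(rc$keep)
      g <- structure(g2, class = "grid_model")
    }
  }
  g
}

rot90 <- function(v) c(-v[2], v[1])  # maps image-right onto image-down

#' Predicted pixel center of lattice nodes
#'
#' @param grid A `grid_model`.
#' @param grid_row,grid_col 0-based lattice indices (vectorized).
#' @return Matrix with columns `x`, `y`.
#' @export
predict_centers <- function(grid, grid_row, grid_col) {
  stopifnot(inherits(grid, "grid_model"))
  cbind(x = grid$origin["x"] + grid_row * grid$row_step["x"] +
          grid_col * grid$col_step["x"],
        y = grid$origin["y"] + grid_row * grid$row_step["y"] +
          grid_col * grid$col_step["y"])
}

#' @export
print.grid_model <- function(x, ...) {
  cat(sprintf(
    "<grid_model> origin (%.2f, %.2f), row step (%.2f, %.2f), col step (%.2f, %.2f), rms %.3g px (%d spots)\n",
    x$origin["x"], x$origin["y"], x$row_step["x"], x$row_step["y"],
    x$col_step["x"], x$col_step["y"], x$rms_residual, x$n_assigned))
  invisible(x)
}

#' Enumerate lattice spots in serpentine order
#'
#' @param grid A `grid_model` from [fit_spot_grid()].
#' @param layout A [pad_layout()].
#' @param index_offset First serpentine index (0-based); use the number of
#'   fractions covered by preceding images when one PAD is imaged in blocks.
#' @return A `spot_table` data.frame (positions only; measurement columns
#'   `NA`), ordered by `serpentine_index`.
#' @export
enumerate_spots <- function(grid, layout, index_offset = 0L) {
  stopifnot(inherits(grid, "grid_model"), inherits(layout, "pad_layout"))
  if (!is_count(index_offset)) abort_validation("index_offset must be >= 0")
  ord <- serpentine_order(layout$n_rows, layout$n_cols)
  ctr <- predict_centers(grid, ord$grid_row, ord$grid_col)
  tab <- data.frame(
    serpentine_index = ord$serpentine_index + as.integer(index_offset),
    label = ord$label,
    grid_row = ord$grid_row, grid_col = ord$grid_col,
    center_x_px = unname(ctr[, "x"]), center_y_px = unname(ctr[, "y"]),
    mean_intensity = NA_real_, halo_radius_px = NA_real_,
    raw_activity = NA_real_, norm_activity = NA_real_,
    source_image = NA_character_,
    stringsAsFactors = FALSE)
  as_spot_table(tab, normalization_median = NA_real_)
}
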
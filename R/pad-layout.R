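#' Describe the spot layout of a uPAD
#'
#' A uPAD carries a rectangular lattice of wax-printed circles; each circle
#' receives one LC fraction.  Rows are lettered top-down (A, B, ...), columns
#' numbered left-right (1, 2, ...), and spotting follows a serpentine
#' (boustrophedon) path starting at A1 so that consecutive fractions stay
#' spatially adjacent.  When a large PAD is imaged in blocks (the typical
#' acquisition covers 10 x 10 spots per image), `block_shape` records that
#' grouping and [merge_spot_tables()] reassembles the full fraction series.
#'
#' @param n_rows,n_cols Lattice dimensions (spots).
#' @param pitch Center-to-center spot spacing in pixels.
#' @param spot_radius Expected spot radius in pixels; must satisfy
#'   `pitch > 2 * spot_radius`.
#' @param serpentine_origin Corner where fraction 0 sits; only `"top-left"`
#'   is currently implemented.
#' @param block_shape Integer pair `(rows, cols)` of spots covered by one
#'   image, default `c(10, 10)`.
#' @return A `pad_layout` object.
#' @export
pad_layout <- function(n_rows, n_cols, pitch, spot_radius,
                       serpentine_origin = "top-left",
                       block_shape = c(10L, 10L)) {
  if (!is_count(n_rows) || !is_count(n_cols) || n_rows * n_cols < 1)
    abort_validation("n_rows and n_cols must be positive counts")
  if (!is_number(pitch) || !is_number(spot_radius) || spot_radius <= 0)
    abort_validation("pitch and spot_radius must be positive numbers")
  if (pitch <= 2 * spot_radius)
    abort_validation("pitch (%.3g) must exceed twice the spot radius (%.3g)",
                     pitch, 2 * spot_radius)
  serpentine_origin <- match.arg(serpentine_origin, "top-left")
  block_shape <- as.integer(block_shape)
  if (length(block_shape) != 2L || any(block_shape < 1L))
    abort_validation("block_shape must be two positive integers")
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 pitch = pitch, spot_radius = spot_radius,
                 serpentine_origin = serpentine_origin,
                 block_shape = block_shape),
            class = "pad_layout")
}

#' @export
print.pad_layout <- function(x, ...) {
  cat(sprintf(
    "<pad_layout> %d x %d spots, pitch %.3g px, spot radius %.3g px, blocks %d x %d\n",
    x$n_rows, x$n_cols, x$pitch, x$spot_radius,
    x$block_shape[1], x$block_shape[2]))
  invisible(x)
}

# Row letters: A..Z then AA, AB, ... (spreadsheet style).
row_letter <- function(r) {
  vapply(as.integer(r), function(i) {
    s <- ""
    i <- i + 1L
    while (i > 0L) {
      s <- paste0(LETTERS[(i - 1L) %% 26L + 1L], s)
      i <- (i - 1L) %/% 26L
    }
    s
  }, character(1))
}

#' Serpentine fraction order of a lattice
#'
#' Fraction 0 is at grid position (0, 0) (top-left); even rows run
#' left-to-right, odd rows right-to-left.
#'
#' @param n_rows,n_cols Lattice dimensions.
#' @return A data.frame with `serpentine_index`, `grid_row`, `grid_col`,
#'   `label`, ordered by index.
#' @export
serpentine_order <- function(n_rows, n_cols) {
  rows <- rep(seq_len(n_rows) - 1L, each = n_cols)
  cols <- unlist(lapply(seq_len(n_rows) - 1L, function(r) {
    cs <- seq_len(n_cols) - 1L
    if (r %% 2L == 1L) rev(cs) else cs
  }))
  data.frame(serpentine_index = seq_along(rows) - 1L,
             grid_row = rows, grid_col = cols,
             label = paste0(row_letter(rows), cols + 1L),
             stringsAsFactors = FALSE)
}
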
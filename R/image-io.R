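#' Load a uPAD luminescence image
#'
#' Reads a grayscale or RGB PNG and returns an intensity image in which
#' luminescence is bright.  Cameras that export luminescence with inverted
#' gray values (dark spots on a light background, common when contrast is
#' enhanced for display) are handled by `invert = TRUE`, which maps
#' `pixels' = max(pixels) - pixels`.  RGB input is collapsed to luminance by
#' the channel mean; inversion is always explicit, never auto-detected.
#'
#' @param path Path to a PNG file (8- or 16-bit, gray or RGB).  TIFF is not
#'   supported; convert to PNG first.
#' @param invert If `TRUE`, invert gray values so that luminescence is bright.
#' @return An `intensity_image`: a list with `pixels` (numeric matrix, row =
#'   image row, origin top-left, values in `[0, 1]` for file input),
#'   `inverted` and `source`.
#' @seealso [as_intensity_image()] for in-memory matrices,
#'   [analyze_upad_image()] for the full densitometry chain.
#' @export
load_luminescence_image <- function(path, invert = FALSE) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    abort_io("cannot read image file '%s'", as.character(path)[1])
  px <- tryCatch(png::readPNG(path), error = function(e)
    abort_io("failed to read PNG '%s': %s", path, conditionMessage(e)))
  if (length(dim(px)) == 3L) px <- rowMeans(px, dims = 2L)  # RGB(A) -> luminance
  as_intensity_image(px, invert = invert, source = path)
}

#' Coerce a numeric matrix to an intensity image
#'
#' @param pixels Nonnegative numeric matrix, row-major with origin top-left.
#' @param invert If `TRUE`, apply `max(pixels) - pixels`.
#' @param source Optional provenance string.
#' @return An `intensity_image` object.
#' @export
as_intensity_image <- function(pixels, invert = FALSE, source = NA_character_) {
  if (inherits(pixels, "intensity_image")) return(pixels)
  if (!is.matrix(pixels) || !is.numeric(pixels))
    abort_validation("pixels must be a numeric matrix")
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    abort_validation("zero-size image")
  if (anyNA(pixels) || any(pixels < 0))
    abort_validation("pixel values must be finite and nonnegative")
  if (isTRUE(invert)) pixels <- max(pixels) - pixels
  structure(list(pixels = pixels, inverted = isTRUE(invert),
                 source = source),
            class = "intensity_image")
}

#' @export
print.intensity_image <- function(x, ...) {
  cat(sprintf("<intensity_image> %d x %d px, range [%.4g, %.4g]%s\n",
              nrow(x$pixels), ncol(x$pixels), min(x$pixels), max(x$pixels),
              if (x$inverted) ", inverted on load" else ""))
  invisible(x)
}

#' Write an intensity image to PNG
#'
#' Values are clipped to `[0, 1]`; use `scale` to map arbitrary intensity
#' units onto the file range first.
#'
#' @param img An `intensity_image` or numeric matrix.
#' @param path Output PNG path.
#' @param scale Divisor applied before writing (default 1).
#' @return `path`, invisibly.
#' @export
write_luminescence_image <- function(img, path, scale = 1) {
  img <- as_intensity_image(img)
  px <- pmin(pmax(img$pixels / scale, 0), 1)
  ok <- tryCatch({ png::writePNG(px, target = path); TRUE },
                 error = function(e) FALSE)
  if (!ok) abort_io("cannot write PNG '%s'", path)
  invisible(path)
}
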
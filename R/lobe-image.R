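#' Construct a calibrated lobe image
#'
#' Bundles an 8-bit RGB pixel array with the spatial calibration (mm per
#' pixel, derived from a printed reference grid photographed next to the
#' lobe) and the lobe selection mask inside which burden is quantified.
#'
#' @param pixels H x W x 3 array of integer intensities in 0..255
#'   (channel order R, G, B).
#' @param mm_per_px Side length of one pixel in mm (> 0). A 5 x 5 mm grid
#'   square spanning 100 px per side gives `mm_per_px = 0.05`.
#' @param lobe_mask H x W logical matrix marking the lobe selection;
#'   defaults to the whole frame.
#' @return An object of class `lobe_image`.
#' @export
lobe_image <- function(pixels, mm_per_px, lobe_mask = NULL) {
  if (length(dim(pixels)) != 3 || dim(pixels)[3] != 3) {
    abort("`pixels` must be an H x W x 3 RGB array.")
  }
  if (min(pixels) < 0 || max(pixels) > 255) {
    abort("`pixels` intensities must lie in 0..255.")
  }
  if (!is.numeric(mm_per_px) || length(mm_per_px) != 1 || mm_per_px <= 0) {
    abort("`mm_per_px` must be a single positive number.")
  }
  if (is.null(lobe_mask)) {
    lobe_mask <- matrix(TRUE, dim(pixels)[1], dim(pixels)[2])
  }
  if (!is.logical(lobe_mask) ||
      !identical(dim(lobe_mask), dim(pixels)[1:2])) {
    abort("`lobe_mask` must be a logical H x W matrix matching `pixels`.")
  }
  if (!any(lobe_mask)) abort("`lobe_mask` must be nonempty.")
  structure(
    list(pixels = pixels, mm_per_px = mm_per_px, lobe_mask = lobe_mask),
    class = "lobe_image"
  )
}

#' @export
print.lobe_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<lobe_image> %d x %d px, %.4g mm/px, lobe %d px (%.1f mm^2)\n",
              d[1], d[2], x$mm_per_px, sum(x$lobe_mask),
              sum(x$lobe_mask) * x$mm_per_px^2))
  invisible(x)
}

#' Read / write a lobe photograph as 8-bit RGB PNG
#'
#' `read_lobe_png()` loads an RGB PNG and attaches the calibration; an
#' optional single-channel mask PNG (nonzero = inside the lobe) supplies the
#' lobe selection. `write_lobe_png()` writes the pixel array back out.
#'
#' @param path PNG file path.
#' @param mm_per_px Calibration, mm per pixel.
#' @param mask_path Optional path to a grayscale mask PNG.
#' @return `read_lobe_png()` returns a [lobe_image()]; `write_lobe_png()`
#'   returns `path` invisibly.
#' @export
read_lobe_png <- function(path, mm_per_px, mask_path = NULL) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) != 3) abort("PNG must have colour channels.")
  arr <- arr[, , 1:3, drop = FALSE]  # drop alpha if present
  mask <- NULL
  if (!is.null(mask_path)) {
    m <- png::readPNG(mask_path)
    if (length(dim(m)) == 3) m <- m[, , 1]
    mask <- m > 0
  }
  lobe_image(round(arr * 255), mm_per_px, mask)
}

#' @rdname read_lobe_png
#' @param image A [lobe_image()] or H x W x 3 array in 0..255.
#' @export
write_lobe_png <- function(image, path) {
  px <- if (inherits(image, "lobe_image")) image$pixels else image
  png::writePNG(px / 255, path)
  invisible(path)
}
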
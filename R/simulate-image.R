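#' Specify a synthetic lobe photograph
#'
#' Emulates a dissected lung lobe photographed against a calibration grid:
#' an elliptical lobe of lighter lung tissue carrying circular, dark
#' melanized nodules. Melanin absorbs strongly, so nodules must be darker
#' than lung tissue in the red channel (`nodule_red_level < lung_red_level`).
#' The green and blue channels carry independent clutter, so quantification
#' must rely on the red channel alone.
#'
#' @param lobe_axes Length-2 integer vector, ellipse semi-axes in pixels
#'   (rows, cols).
#' @param nodule_count Number of nodules painted (may merge by overlap).
#' @param nodule_radius_px Nodule radius in pixels.
#' @param lung_red_level Red intensity of tumor-free lung tissue (0..255).
#' @param nodule_red_level Red intensity inside nodules (0..255, darker).
#' @param pixel_noise_sd Gaussian pixel noise SD in gray levels.
#' @param mm_per_px Calibration, mm per pixel.
#' @param seed Integer seed.
#' @return An object of class `image_spec`.
#' @seealso [simulate_lobe_image()]
#' @export
image_spec <- function(lobe_axes = c(60, 90),
                       nodule_count = 8,
                       nodule_radius_px = 6,
                       lung_red_level = 160,
                       nodule_red_level = 40,
                       pixel_noise_sd = 4,
                       mm_per_px = 0.05,
                       seed = 1L) {
  if (length(lobe_axes) != 2 || any(lobe_axes < 2)) {
    abort("`lobe_axes` must be two semi-axes of at least 2 px.")
  }
  levels <- c(lung_red_level, nodule_red_level)
  if (any(levels < 0) || any(levels > 255)) {
    abort("Intensity levels must lie in 0..255.")
  }
  if (nodule_red_level >= lung_red_level) {
    abort("`nodule_red_level` must be below `lung_red_level`: melanized nodules are dark.")
  }
  if (nodule_count > 0 && nodule_radius_px >= min(lobe_axes)) {
    abort("`nodule_radius_px` must be smaller than the lobe semi-axes.")
  }
  if (pixel_noise_sd < 0) abort("`pixel_noise_sd` must be >= 0.")
  structure(
    list(
      lobe_axes = as.numeric(lobe_axes),
      nodule_count = as.integer(nodule_count),
      nodule_radius_px = as.numeric(nodule_radius_px),
      lung_red_level = lung_red_level,
      nodule_red_level = nodule_red_level,
      pixel_noise_sd = pixel_noise_sd,
      mm_per_px = mm_per_px,
      seed = as.integer(seed)
    ),
    class = "image_spec"
  )
}

#' Simulate a lobe photograph with known ground truth
#'
#' Paints the lobe ellipse at the lung red level, then `nodule_count` dark
#' circular nodules fully inside the lobe, adds Gaussian pixel noise, and
#' fills green/blue with independent clutter. Ground truth is recorded from
#' the painted mask before noise: the tumor fraction is painted nodule
#' pixels over lobe pixels, and the nodule count is the number of merged
#' connected components (overlapping nodules count once).
#'
#' @param spec An [image_spec()].
#' @return A list with `image` (a [lobe_image()]) and `truth`
#'   (list: `tumor_fraction`, `nodule_count`, `tumor_mask`).
#' @examples
#' sim <- simulate_lobe_image(image_spec(seed = 3))
#' sim$truth$tumor_fraction
#' @export
simulate_lobe_image <- function(spec) {
  stopifnot(inherits(spec, "image_spec"))
  a <- spec$lobe_axes[1]; b <- spec$lobe_axes[2]
  margin <- 6
  nr <- as.integer(2 * (a + margin)); nc <- as.integer(2 * (b + margin))
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  row_i <- matrix(seq_len(nr), nr, nc)
  col_i <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  lobe_mask <- ((row_i - cy) / a)^2 + ((col_i - cx) / b)^2 <= 1

  with_seed(spec$seed, {
    tumor_mask <- matrix(FALSE, nr, nc)
    if (spec$nodule_count > 0) {
      r <- spec$nodule_radius_px
      # centers drawn so the whole disk stays inside the ellipse
      fits <- ((row_i - cy) / (a - r))^2 + ((col_i - cx) / (b - r))^2 <= 1
      centers <- sample(which(fits), spec$nodule_count, replace = TRUE)
      for (ct in centers) {
        rr <- (ct - 1L) %% nr + 1L
        cc <- (ct - 1L) %/% nr + 1L
        tumor_mask <- tumor_mask | ((row_i - rr)^2 + (col_i - cc)^2 <= r^2)
      }
      tumor_mask <- tumor_mask & lobe_mask
    }

    background <- 10
    red <- matrix(background, nr, nc)
    red[lobe_mask] <- spec$lung_red_level
    red[tumor_mask] <- spec$nodule_red_level
    if (spec$pixel_noise_sd > 0) {
      red <- red + rnorm(nr * nc, sd = spec$pixel_noise_sd)
    }
    # green/blue clutter is independent of tumor content on purpose
    green <- matrix(runif(nr * nc, 0, 255), nr, nc)
    blue <- matrix(runif(nr * nc, 0, 255), nr, nc)
    px <- array(0, dim = c(nr, nc, 3))
    px[, , 1] <- pmin(pmax(round(red), 0), 255)
    px[, , 2] <- round(green)
    px[, , 3] <- round(blue)

    list(
      image = lobe_image(px, spec$mm_per_px, lobe_mask),
      truth = list(
        tumor_fraction = sum(tumor_mask) / sum(lobe_mask),
        nodule_count = max(label_components(tumor_mask)),
        tumor_mask = tumor_mask
      )
    )
  })
}
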
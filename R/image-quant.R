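#' Extract the red channel of an RGB image
#'
#' Quantification uses the red channel only: blood, bruising and other
#' discoloration contaminate green and blue far more than red, while
#' melanized nodules absorb strongly in red. Returns the first channel
#' untouched.
#'
#' @param image A [lobe_image()] or an H x W x 3 array.
#' @return An H x W numeric matrix of red intensities.
#' @export
red_channel <- function(image) {
  px <- if (inherits(image, "lobe_image")) image$pixels else image
  if (length(dim(px)) != 3 || dim(px)[3] != 3) {
    abort("Expected a 3-channel RGB image.")
  }
  px[, , 1]
}

#' Kapur maximum-entropy threshold
#'
#' Selects the gray level `t` maximizing the sum of Shannon entropies of the
#' two classes the histogram is split into: levels `<= t` and levels `> t`
#' (natural log; empty bins contribute zero). Candidate thresholds that
#' leave either class empty are excluded; exact ties are broken toward the
#' lowest qualifying level. This is the classical "MaxEntropy"
#' auto-threshold used for segmenting nodules from lung tissue.
#'
#' @param histogram 256 nonnegative counts for gray levels 0..255, or an
#'   image/matrix of intensities in 0..255 from which the histogram is
#'   tabulated.
#' @return The threshold level, an integer in 0..255.
#' @examples
#' h <- numeric(256); h[c(51, 201)] <- 500  # levels 50 and 200
#' kapur_threshold(h)
#' @export
kapur_threshold <- function(histogram) {
  h <- as_histogram256(histogram)
  if (sum(h > 0) < 2) {
    abort("Histogram is degenerate (fewer than two occupied gray levels): no threshold.")
  }
  p <- h / sum(h)
  plogp <- ifelse(p > 0, p * log(p), 0)
  cum_p <- cumsum(p)
  cum_plogp <- cumsum(plogp)
  # candidate thresholds t = 0..254 (index i = t + 1); both classes nonempty
  i <- seq_len(255)
  p_low <- cum_p[i]
  p_high <- 1 - p_low
  valid <- p_low > 0 & cumsum(h)[i] < sum(h)
  h_low <- ifelse(valid, log(p_low) - cum_plogp[i] / p_low, -Inf)
  h_high <- ifelse(valid, log(p_high) - (sum(plogp) - cum_plogp[i]) / p_high, -Inf)
  total <- h_low + h_high
  as.integer(which.max(total) - 1L)  # which.max takes the first (lowest) tie
}

as_histogram256 <- function(x) {
  if (is.numeric(x) && length(x) == 256 && is.null(dim(x))) {
    if (any(x < 0)) abort("Histogram counts must be nonnegative.")
    return(x)
  }
  v <- as.vector(if (inherits(x, "lobe_image")) red_channel(x) else x)
  if (any(v < 0) || any(v > 255)) abort("Intensities must lie in 0..255.")
  tabulate(as.integer(round(v)) + 1L, nbins = 256)
}

#' Label connected components of a binary mask
#'
#' Two foreground pixels belong to the same component if they touch at an
#' edge or a corner (8-connectivity). Iterative flood fill; no recursion.
#'
#' @param mask Logical matrix.
#' @return Integer matrix of the same shape: 0 for background, 1..n for
#'   component membership. `max()` of the result is the component count.
#' @export
label_components <- function(mask) {
  if (!is.logical(mask) || !is.matrix(mask)) {
    abort("`mask` must be a logical matrix.")
  }
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  if (!any(mask)) return(lab)
  stack <- integer(sum(mask))
  cur <- 0L
  for (i in which(mask)) {
    if (lab[i] > 0L) next
    cur <- cur + 1L
    lab[i] <- cur
    stack[1L] <- i
    top <- 1L
    while (top > 0L) {
      j <- stack[top]; top <- top - 1L
      r <- (j - 1L) %% nr + 1L
      c <- (j - 1L) %/% nr + 1L
      for (dr in -1L:1L) {
        rr <- r + dr
        if (rr < 1L || rr > nr) next
        for (dc in -1L:1L) {
          cc <- c + dc
          if (cc < 1L || cc > nc) next
          k <- (cc - 1L) * nr + rr
          if (mask[k] && lab[k] == 0L) {
            lab[k] <- cur
            top <- top + 1L
            stack[top] <- k
          }
        }
      }
    }
  }
  lab
}

#' Count nodules in a binary tumor mask
#'
#' Counts 8-connected components with at least `min_px` pixels; smaller
#' specks are treated as segmentation noise.
#'
#' @param mask Logical matrix (tumor = TRUE).
#' @param min_px Minimum component size in pixels (default 5).
#' @return Integer count.
#' @export
count_nodules <- function(mask, min_px = 5) {
  lab <- label_components(mask)
  if (max(lab) == 0L) return(0L)
  sizes <- tabulate(lab[lab > 0L])
  sum(sizes >= min_px)
}

#' Quantify tumor burden on a lobe photograph
#'
#' Takes the red-channel histogram over the lobe selection, computes the
#' Kapur maximum-entropy threshold, and assigns the dark class (red
#' intensity at or below the threshold) to tumor: melanized nodules have
#' low red intensity. Pixel counts convert to mm^2 through the grid
#' calibration (`mm_per_px^2` per pixel). Set `tumor_dark = FALSE` for
#' non-melanized tumors that segment as the bright class.
#'
#' @param image A [lobe_image()].
#' @param min_px Minimum nodule size in pixels for counting.
#' @param tumor_dark If `TRUE` (default) tumor is the at-or-below-threshold
#'   class.
#' @return A one-row tibble: `tumor_fraction`, `tumor_area_mm2`,
#'   `lobe_area_mm2`, `threshold_level`, `nodule_count`, `degenerate`.
#'   A lobe whose red histogram occupies a single level (no segmentable
#'   contrast) is reported as zero burden with `degenerate = TRUE` and a
#'   warning.
#' @examples
#' sim <- simulate_lobe_image(image_spec(seed = 1))
#' quantify_lobe(sim$image)
#' @export
quantify_lobe <- function(image, min_px = 5, tumor_dark = TRUE) {
  stopifnot(inherits(image, "lobe_image"))
  red <- red_channel(image)
  lobe_px <- sum(image$lobe_mask)
  lobe_area <- lobe_px * image$mm_per_px^2
  h <- as_histogram256(red[image$lobe_mask])
  if (sum(h > 0) < 2) {
    warn("Red histogram over the lobe is degenerate; reporting zero burden.")
    return(tibble(
      tumor_fraction = 0, tumor_area_mm2 = 0, lobe_area_mm2 = lobe_area,
      threshold_level = NA_integer_, nodule_count = 0L, degenerate = TRUE
    ))
  }
  thr <- kapur_threshold(h)
  tumor_mask <- if (tumor_dark) red <= thr else red > thr
  tumor_mask <- tumor_mask & image$lobe_mask
  tumor_px <- sum(tumor_mask)
  tibble(
    tumor_fraction = tumor_px / lobe_px,
    tumor_area_mm2 = tumor_px * image$mm_per_px^2,
    lobe_area_mm2 = lobe_area,
    threshold_level = as.integer(thr),
    nodule_count = count_nodules(tumor_mask, min_px = min_px),
    degenerate = FALSE
  )
}
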
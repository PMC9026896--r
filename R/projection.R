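#' Configure single-timepoint survival projection
#'
#' Projection freezes a cohort-calibrated growth exponent and lets only the
#' per-mouse amplitude A0 vary, reflecting individual engraftment. A mouse
#' measured at burden `a` on day `d` gets `A0_i = a / d^B` (power) or
#' `A0_i = a * exp(-k d)` (exponential); its projected survival time is the
#' day its curve crosses the critical burden threshold.
#'
#' @param family `"power"` (default, as used for the projected survival
#'   curves) or `"exponential"`.
#' @param exponent Cohort-calibrated B or k (> 0). May also be a
#'   [growth_fit()], whose family and exponent are adopted.
#' @param threshold_mm2 Critical lung tumor area defining projected death;
#'   default 300 mm^2.
#' @return An object of class `projection_config`.
#' @export
projection_config <- function(family = c("power", "exponential"),
                              exponent = 4.1,
                              threshold_mm2 = 300) {
  if (inherits(exponent, "growth_fit")) {
    family <- exponent$family
    exponent <- exponent$exponent
  } else {
    family <- match.arg(family)
  }
  if (!is.numeric(exponent) || length(exponent) != 1 || exponent <= 0) {
    abort("`exponent` must be a single positive number.")
  }
  if (!is.numeric(threshold_mm2) || length(threshold_mm2) != 1 ||
      threshold_mm2 <= 0) {
    abort("`threshold_mm2` must be a single positive area.")
  }
  structure(
    list(family = family, exponent = exponent, threshold_mm2 = threshold_mm2),
    class = "projection_config"
  )
}

#' Project one mouse's threshold-crossing day
#'
#' @param area Measured tumor area (mm^2) at sacrifice; must be > 0 for a
#'   defined projection.
#' @param day Measurement day (> 0).
#' @param config A [projection_config()].
#' @return One-row tibble: `amplitude_i` (best-fit per-mouse A0),
#'   `crossing_day` (projected survival time, days), and `above_threshold`
#'   (TRUE when the mouse was already past the threshold at measurement,
#'   so the crossing is projected into the past).
#' @examples
#' project_mouse(50, 14, projection_config("exponential", 0.45))
#' @export
project_mouse <- function(area, day, config) {
  stopifnot(inherits(config, "projection_config"))
  if (length(area) != 1 || length(day) != 1) {
    abort("`project_mouse` takes a single (area, day); use `project_cohort` for tables.")
  }
  if (day <= 0) abort("`day` must be strictly positive.")
  if (is.na(area) || area <= 0) {
    abort("Projection undefined for zero/missing area; handle via `project_cohort`.")
  }
  thr <- config$threshold_mm2
  b <- config$exponent
  if (config$family == "power") {
    amplitude_i <- area / day^b
    crossing <- (thr / amplitude_i)^(1 / b)
  } else {
    amplitude_i <- area * exp(-b * day)
    crossing <- log(thr / amplitude_i) / b
  }
  tibble(amplitude_i = amplitude_i, crossing_day = crossing,
         above_threshold = area >= thr & crossing <= day)
}

#' Project survival for a single-timepoint cohort
#'
#' Applies [project_mouse()] to every row (one record per mouse). Zero-area
#' mice have no estimable growth curve; they are flagged and enter the
#' projected Kaplan-Meier analysis right-censored at their measurement day.
#' Mice already above the threshold get a crossing day before their
#' measurement day; since a projected death cannot predate an observed
#' survival, their event time for KM is their measurement day (flagged).
#'
#' @param data Data frame with one row per mouse: `mouse_id`, `area_mm2`,
#'   `day` (and optionally `group`).
#' @param config A [projection_config()].
#' @return A tibble of class `projection`: input columns plus
#'   `amplitude_i`, `crossing_day`, `above_threshold`, `zero_area`,
#'   `km_time`, `km_event`. `glance()` gives the median projected survival.
#' @examples
#' sim <- simulate_cohort(cohort_spec(seed = 5))
#' d14 <- dplyr::filter(sim, day == 14)
#' project_cohort(d14, projection_config("power", 4.1))
#' @export
project_cohort <- function(data, config) {
  stopifnot(inherits(config, "projection_config"))
  stopifnot(all(c("mouse_id", "area_mm2", "day") %in% names(data)))
  if (anyDuplicated(data$mouse_id)) {
    abort("One record per mouse required; duplicated `mouse_id` found.")
  }
  res <- purrr::pmap_dfr(
    list(data$area_mm2, data$day),
    function(a, d) {
      if (is.na(a) || a <= 0) {
        tibble(amplitude_i = NA_real_, crossing_day = NA_real_,
               above_threshold = FALSE)
      } else {
        project_mouse(a, d, config)
      }
    }
  )
  out <- dplyr::bind_cols(as_tibble(data), res)
  out$zero_area <- is.na(out$crossing_day)
  out$km_time <- dplyr::case_when(
    out$zero_area ~ out$day,
    out$above_threshold ~ out$day,
    TRUE ~ out$crossing_day
  )
  out$km_event <- !out$zero_area
  class(out) <- c("projection", class(out))
  attr(out, "config") <- config
  out
}

#' @rdname project_cohort
#' @param x A `projection` tibble.
#' @param ... Unused.
#' @export
glance.projection <- function(x, ...) {
  tibble(
    n = nrow(x),
    n_zero_area = sum(x$zero_area),
    n_above_threshold = sum(x$above_threshold),
    median_crossing_day = stats::median(x$crossing_day, na.rm = TRUE),
    family = attr(x, "config")$family,
    exponent = attr(x, "config")$exponent,
    threshold_mm2 = attr(x, "config")$threshold_mm2
  )
}
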
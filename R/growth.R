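#' Construct a growth fit directly from known parameters
#'
#' Builds a `growth_fit` object without data, e.g. to evaluate published
#' parameter sets. `Area = A0 * t^B` (power) or `Area = A0 * exp(k * t)`
#' (exponential).
#'
#' @param family `"power"` or `"exponential"`.
#' @param amplitude A0 in mm^2 (> 0).
#' @param exponent B (unitless) or k (per day).
#' @return An object of class `growth_fit`.
#' @export
growth_fit <- function(family = c("power", "exponential"), amplitude, exponent) {
  family <- match.arg(family)
  if (!is.numeric(amplitude) || length(amplitude) != 1 || amplitude <= 0) {
    abort("`amplitude` must be a single positive number (mm^2).")
  }
  structure(
    list(family = family, amplitude = amplitude, exponent = exponent,
         stderr_exponent = NA_real_, residual_sd_log = NA_real_,
         n_obs = NA_integer_, n_zero_excluded = 0L, r_squared = NA_real_),
    class = "growth_fit"
  )
}

#' Reference growth fits for B16F10 lung metastases
#'
#' The calibrated growth laws for CD47-knockout B16F10 lung metastasis
#' cohorts: power-law fits for untreated controls (A0 = 0.0019 mm^2,
#' B = 4.1) and anti-Tyrp1-treated mice (A0 = 0.0087 mm^2, B = 3.0), and
#' the exponential description of untreated growth (A0 = 0.05 mm^2,
#' k = 0.45 per day). Areas are lung-surface tumor areas in mm^2, days are
#' post-inoculation.
#'
#' @return A named list of [growth_fit()] objects:
#'   `power_untreated`, `power_treated`, `exponential_untreated`.
#' @export
reference_growth_fits <- function() {
  list(
    power_untreated = growth_fit("power", 0.0019, 4.1),
    power_treated = growth_fit("power", 0.0087, 3.0),
    exponential_untreated = growth_fit("exponential", 0.05, 0.45)
  )
}

#' Fit a growth law to a cross-sectional cohort
#'
#' Ordinary least squares on log-transformed coordinates:
#' `ln(area) ~ ln(day)` for the power law, `ln(area) ~ day` for the
#' exponential. Every record is an independent observation (each mouse is
#' sacrificed once, so there are no repeated measures). Log-space fitting
#' matches the multiplicative error structure of engraftment and
#' measurement noise. Zero-area records have no logarithm; they are
#' excluded and counted in `n_zero_excluded` (optionally floored instead
#' via `floor_mm2`).
#'
#' @param data Data frame with columns `day` and `area_mm2`.
#' @param family `"power"` or `"exponential"`.
#' @param floor_mm2 Optional positive floor applied to areas before the log
#'   transform (keeps zero-area mice in the fit). Default `NULL`: exclude.
#' @return A `growth_fit` with `amplitude` (= exp(intercept)), `exponent`
#'   (slope), `stderr_exponent`, `residual_sd_log`, `n_obs`,
#'   `n_zero_excluded`, `r_squared`.
#' @examples
#' sim <- simulate_cohort(cohort_spec(seed = 1))
#' fit_growth(sim, "power")
#' @export
fit_growth <- function(data, family = c("power", "exponential"),
                       floor_mm2 = NULL) {
  family <- match.arg(family)
  stopifnot(all(c("day", "area_mm2") %in% names(data)))
  day <- data$day
  area <- data$area_mm2
  if (any(day <= 0)) abort("All `day` values must be strictly positive for fitting.")
  if (any(area < 0)) abort("`area_mm2` must be nonnegative.")
  if (!is.null(floor_mm2)) {
    stopifnot(floor_mm2 > 0)
    area <- pmax(area, floor_mm2)
  }
  keep <- area > 0
  n_zero <- sum(!keep)
  day <- day[keep]; area <- area[keep]
  if (length(area) < 2) abort("Need at least 2 records with positive area.")
  if (length(unique(day)) < 2) abort("Need records at >= 2 distinct days.")
  x <- if (family == "power") log(day) else day
  fit <- lm(log(area) ~ x)
  st <- lm_stats(fit)
  structure(
    list(
      family = family,
      amplitude = exp(unname(coef(fit)[1])),
      exponent = unname(coef(fit)[2]),
      stderr_exponent = st$se_slope,
      residual_sd_log = st$sigma,
      n_obs = length(area),
      n_zero_excluded = n_zero,
      r_squared = st$r_squared
    ),
    class = "growth_fit"
  )
}

#' @export
print.growth_fit <- function(x, ...) {
  sym <- if (x$family == "power") "B" else "k"
  form <- if (x$family == "power") "A0 * t^%s" else "A0 * exp(%s t)"
  cat(sprintf("<growth_fit> Area = %s\n", sprintf(form, sym)))
  cat(sprintf("  A0 = %.4g mm^2, %s = %.4g", x$amplitude, sym, x$exponent))
  if (!is.na(x$stderr_exponent)) cat(sprintf(" (SE %.3g)", x$stderr_exponent))
  cat("\n")
  if (!is.na(x$n_obs)) {
    cat(sprintf("  n = %d records", x$n_obs))
    if (x$n_zero_excluded > 0) {
      cat(sprintf(" (%d zero-area excluded)", x$n_zero_excluded))
    }
    cat("\n")
  }
  invisible(x)
}

#' @rdname fit_growth
#' @param x A `growth_fit`.
#' @param ... Unused.
#' @export
tidy.growth_fit <- function(x, ...) {
  tibble(
    term = c("amplitude", "exponent"),
    estimate = c(x$amplitude, x$exponent),
    std.error = c(NA_real_, x$stderr_exponent)
  )
}

#' @rdname fit_growth
#' @export
glance.growth_fit <- function(x, ...) {
  tibble(
    family = x$family, amplitude = x$amplitude, exponent = x$exponent,
    stderr_exponent = x$stderr_exponent, residual_sd_log = x$residual_sd_log,
    r.squared = x$r_squared, n_obs = x$n_obs,
    n_zero_excluded = x$n_zero_excluded
  )
}

#' Predict tumor area from a growth fit
#'
#' @param fit A [growth_fit()].
#' @param day Day(s) post-inoculation (> 0 for the power family).
#' @return Predicted area(s) in mm^2.
#' @examples
#' predict_area(reference_growth_fits()$power_untreated, 16)
#' @export
predict_area <- function(fit, day) {
  stopifnot(inherits(fit, "growth_fit"))
  if (fit$family == "power" && any(day <= 0)) {
    abort("Power-law prediction requires day > 0.")
  }
  fit$amplitude * growth_factor(fit$family, fit$exponent, day)
}

#' Tumor doubling time under a growth law
#'
#' Exponential growth doubles in `ln(2)/k` days regardless of size. Power-law
#' growth decelerates in relative terms: at area S the burden doubles in
#' `t(S) * (2^(1/B) - 1)` days, where `t(S) = (S / A0)^(1/B)` is the day the
#' curve reaches S.
#'
#' @param fit A [growth_fit()] with positive exponent.
#' @param at_area Area (mm^2) at which the doubling time is evaluated;
#'   required for the power family, ignored for exponential.
#' @return Doubling time in days.
#' @export
doubling_time <- function(fit, at_area = NULL) {
  stopifnot(inherits(fit, "growth_fit"))
  if (fit$exponent <= 0) abort("Doubling time requires a positive growth exponent.")
  if (fit$family == "exponential") return(log(2) / fit$exponent)
  if (is.null(at_area) || any(at_area <= 0)) {
    abort("Power-law doubling time needs `at_area` > 0.")
  }
  t_at <- (at_area / fit$amplitude)^(1 / fit$exponent)
  t_at * (2^(1 / fit$exponent) - 1)
}

#' Fold suppression of growth between two fitted cohorts
#'
#' Ratio of the control prediction to the treated prediction at a given day;
#' > 1 means the treatment suppresses burden.
#'
#' @param fit_ctrl,fit_tx [growth_fit()] objects for the control and treated
#'   cohorts.
#' @param day Day(s) post-inoculation (> 0).
#' @return Unitless suppression fold(s).
#' @examples
#' refs <- reference_growth_fits()
#' suppression_fold(refs$power_untreated, refs$power_treated, 16)
#' @export
suppression_fold <- function(fit_ctrl, fit_tx, day) {
  if (any(day <= 0)) abort("`day` must be strictly positive.")
  pred_tx <- predict_area(fit_tx, day)
  if (any(pred_tx == 0)) abort("Treated prediction is zero; fold undefined.")
  predict_area(fit_ctrl, day) / pred_tx
}

#' Variance-mean scaling of cohort burdens
#'
#' For each (group, day) cell with at least two mice, computes the mean and
#' SD of areas, then regresses `log(SD)` on `log(mean)`. A slope of 1
#' (constant coefficient of variation) is the signature of multiplicative
#' mouse-to-mouse variability amplified by deterministic exponential-type
#' growth; a slope of 0.5 would indicate Poisson-like counting noise.
#'
#' @param data Data frame with columns `group`, `day`, `area_mm2`.
#' @return An object of class `vm_scaling` with elements `slope`,
#'   `std.error`, `conf.low`, `conf.high` (95%), `n_cells` and the per-cell
#'   table `cells`. `tidy()` returns the one-row summary; `autoplot()`
#'   draws the log-log scatter with the fitted line.
#' @examples
#' sim <- simulate_cohort(cohort_spec(mice_per_day = 30, seed = 2))
#' tidy(variance_mean_scaling(sim))
#' @export
variance_mean_scaling <- function(data) {
  stopifnot(all(c("group", "day", "area_mm2") %in% names(data)))
  cells <- data |>
    dplyr::group_by(.data$group, .data$day) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_area = mean(.data$area_mm2),
      sd_area = sd(.data$area_mm2),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n >= 2, .data$sd_area > 0, .data$mean_area > 0)
  if (nrow(cells) < 3) {
    abort("Need >= 3 (group, day) cells with >= 2 mice each.")
  }
  fit <- lm(log(sd_area) ~ log(mean_area), data = cells)
  st <- lm_stats(fit)
  slope <- unname(coef(fit)[2])
  half <- if (is.na(st$se_slope)) 0 else stats::qt(0.975, st$df) * st$se_slope
  structure(
    list(
      slope = slope,
      std.error = st$se_slope,
      conf.low = slope - half, conf.high = slope + half,
      n_cells = nrow(cells),
      cells = cells
    ),
    class = "vm_scaling"
  )
}

#' @export
print.vm_scaling <- function(x, ...) {
  cat(sprintf(
    "<vm_scaling> log(SD) vs log(mean) slope = %.3f (95%% CI %.3f..%.3f, %d cells)\n",
    x$slope, x$conf.low, x$conf.high, x$n_cells
  ))
  invisible(x)
}

#' @rdname variance_mean_scaling
#' @param x A `vm_scaling` object.
#' @param ... Unused.
#' @export
tidy.vm_scaling <- function(x, ...) {
  tibble(
    term = "log(mean_area)", estimate = x$slope, std.error = x$std.error,
    conf.low = x$conf.low, conf.high = x$conf.high, n_cells = x$n_cells
  )
}

#' @rdname variance_mean_scaling
#' @param object A `vm_scaling` object.
#' @export
autoplot.vm_scaling <- function(object, ...) {
  ggplot2::ggplot(object$cells,
                  ggplot2::aes(.data$mean_area, .data$sd_area,
                               colour = .data$group)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(ggplot2::aes(group = 1), method = "lm",
                         formula = y ~ x, se = FALSE, colour = "grey30") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Mean tumor area (mm^2)", y = "SD of tumor area (mm^2)",
                  title = sprintf("Variance-mean scaling (slope %.2f)",
                                  object$slope)) +
    ggplot2::theme_minimal()
}

#' Plot a cohort with fitted growth curves
#'
#' @param object A [growth_fit()].
#' @param data Optional cohort data frame to overlay (`day`, `area_mm2`).
#' @param days Range of days for the curve.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.growth_fit <- function(object, data = NULL,
                                days = NULL, ...) {
  if (is.null(days)) {
    days <- if (!is.null(data)) range(data$day) else c(4, 20)
  }
  grid <- tibble(day = seq(days[1], days[2], length.out = 200))
  grid$area_mm2 <- predict_area(object, grid$day)
  p <- ggplot2::ggplot(grid, ggplot2::aes(.data$day, .data$area_mm2)) +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Days post-inoculation", y = "Tumor area (mm^2)") +
    ggplot2::theme_minimal()
  if (!is.null(data)) {
    p <- p + ggplot2::geom_point(data = data, alpha = 0.6)
  }
  p
}
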
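#' Parameters of the growth-versus-phagocytosis model
#'
#' Tumor burden B grows at intrinsic rate `g` and is cleared in proportion
#' to the density of phagocytic macrophages above an inactive baseline:
#' `dB/dt = (g - phi * max(P - P0, 0)) * B`. `P0` is the density of
#' inactivated (non-phagocytic) macrophages; only activated excess
#' phagocytes clear tumor, and a phagocyte deficit cannot boost growth
#' (hence the rectification). Units of P are arbitrary density units; only
#' the product `phi * P` is identifiable from burden data.
#'
#' @param g Intrinsic proliferation rate, per day.
#' @param phi Clearance efficiency, per day per unit phagocyte density
#'   (>= 0).
#' @param p0 Baseline (inactivated) phagocyte density (>= 0).
#' @param b_init Initial burden, mm^2 (> 0).
#' @return An object of class `phago_params`.
#' @export
phago_params <- function(g, phi, p0 = 0, b_init = 1) {
  if (phi < 0) abort("`phi` must be >= 0.")
  if (p0 < 0) abort("`p0` must be >= 0.")
  if (b_init <= 0) abort("`b_init` must be > 0.")
  structure(list(g = g, phi = phi, p0 = p0, b_init = b_init),
            class = "phago_params")
}

#' Net per-capita growth rate under phagocytic suppression
#'
#' @param params A [phago_params()].
#' @param p Phagocyte density (vectorised).
#' @return Net rate `g - phi * max(p - p0, 0)`, per day.
#' @export
net_rate <- function(params, p) {
  stopifnot(inherits(params, "phago_params"))
  params$g - params$phi * pmax(p - params$p0, 0)
}

#' Solve the suppressed-growth ODE
#'
#' With P held fixed the model is linear and solves in closed form:
#' `B(t) = B_init * exp(net_rate * t)`. The sign of the net rate decides
#' growth versus regression; at `g = phi * (P - P0)` the burden is static.
#'
#' @param params A [phago_params()].
#' @param p Phagocyte density (scalar).
#' @param t Time(s) in days, >= 0.
#' @return Burden(s) in mm^2.
#' @examples
#' pars <- phago_params(g = 0.45, phi = 0.3, p0 = 1, b_init = 0.05)
#' solve_burden(pars, p = 1, t = c(0, 7, 14))  # P = P0: unsuppressed
#' @export
solve_burden <- function(params, p, t) {
  stopifnot(inherits(params, "phago_params"))
  if (any(t < 0)) abort("`t` must be >= 0.")
  params$b_init * exp(net_rate(params, p) * t)
}

#' Fit an exponential decay constant to a regression-phase trajectory
#'
#' Least squares of `ln(burden)` on day within the regression window;
#' `tau = -1 / slope`. Intended for the clearance-dominated phase of a
#' treated trajectory, before regrowth sets in (default window 0..8 days).
#'
#' @param traj Data frame with columns `day` and `burden_mm2` (or `burden`).
#' @param window Length-2 day window; points with `window[1] <= day <=
#'   window[2]` and positive burden enter the fit.
#' @return An object of class `decay_fit`: list with `tau` (days), `slope`
#'   (per day), `std.error` (of the slope), `n_obs`, `window`.
#' @examples
#' traj <- simulate_trajectory(trajectory_spec(sample_days = 0:8, seed = 2))
#' fit_decay(traj)$tau
#' @export
fit_decay <- function(traj, window = c(0, 8)) {
  nm <- if ("burden_mm2" %in% names(traj)) "burden_mm2" else "burden"
  stopifnot(all(c("day", nm) %in% names(traj)))
  keep <- traj$day >= window[1] & traj$day <= window[2] & traj[[nm]] > 0
  day <- traj$day[keep]
  burden <- traj[[nm]][keep]
  if (length(day) < 3) {
    abort("Need >= 3 points with positive burden inside the window.")
  }
  fit <- lm(log(burden) ~ day)
  slope <- unname(coef(fit)[2])
  if (slope >= 0) abort("Trajectory does not decay inside the window (slope >= 0).")
  structure(
    list(
      tau = -1 / slope,
      slope = slope,
      std.error = lm_stats(fit)$se_slope,
      n_obs = length(day),
      window = window
    ),
    class = "decay_fit"
  )
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("<decay_fit> exp(-t/tau), tau = %.3f days (n = %d, window %g..%g)\n",
              x$tau, x$n_obs, x$window[1], x$window[2]))
  invisible(x)
}

#' @rdname fit_decay
#' @param x A `decay_fit`.
#' @param ... Unused.
#' @export
tidy.decay_fit <- function(x, ...) {
  tibble(tau_days = x$tau, slope = x$slope, std.error = x$std.error,
         n_obs = x$n_obs)
}

#' Fit burden versus phagocyte density
#'
#' Snapshot relationship across mice at a fixed observation time: fits
#' `ln(B) = c0 - c1 * (P - P0)`, i.e. exponential suppression of burden by
#' activated phagocyte density. `c1` absorbs `phi * t` at the (fixed,
#' unobserved) time, so it is a suppression coefficient per density unit,
#' not phi itself.
#'
#' @param pairs Data frame with columns `p` (phagocyte density) and
#'   `burden_mm2` (or `burden`).
#' @param p0 Baseline density subtracted before fitting.
#' @return An object of class `suppression_fit`: `b0_mm2` (burden at
#'   `P = P0`), `suppression_coef` (c1), `std.error`, `r_squared`, `n_obs`,
#'   and `suppression_violated` (TRUE when burden increases with P).
#' @examples
#' pairs <- tibble::tibble(p = 1:6, burden_mm2 = 100 * exp(-0.3 * (1:6 - 1)))
#' fit_burden_vs_phagocytes(pairs, p0 = 1)
#' @export
fit_burden_vs_phagocytes <- function(pairs, p0 = 0) {
  nm <- if ("burden_mm2" %in% names(pairs)) "burden_mm2" else "burden"
  stopifnot(all(c("p", nm) %in% names(pairs)))
  p <- pairs$p
  b <- pairs[[nm]]
  keep <- b > 0
  p <- p[keep]; b <- b[keep]
  if (length(p) < 3) abort("Need >= 3 pairs with positive burden.")
  if (length(unique(p)) < 2) abort("Degenerate phagocyte densities: all equal.")
  x <- p - p0
  fit <- lm(log(b) ~ x)
  c1 <- -unname(coef(fit)[2])
  violated <- c1 < 0
  if (violated) {
    warn("Burden increases with phagocyte density: suppression sign violated.")
  }
  st <- lm_stats(fit)
  structure(
    list(
      b0_mm2 = exp(unname(coef(fit)[1])),
      suppression_coef = c1,
      std.error = st$se_slope,
      r_squared = st$r_squared,
      n_obs = length(p),
      suppression_violated = violated
    ),
    class = "suppression_fit"
  )
}

#' @export
print.suppression_fit <- function(x, ...) {
  cat(sprintf("<suppression_fit> B = %.4g * exp(-%.4g * (P - P0)), n = %d\n",
              x$b0_mm2, x$suppression_coef, x$n_obs))
  if (x$suppression_violated) cat("  WARNING: suppression sign violated\n")
  invisible(x)
}

#' @rdname fit_burden_vs_phagocytes
#' @param x A `suppression_fit`.
#' @param ... Unused.
#' @export
tidy.suppression_fit <- function(x, ...) {
  tibble(b0_mm2 = x$b0_mm2, suppression_coef = x$suppression_coef,
         std.error = x$std.error, r.squared = x$r_squared, n_obs = x$n_obs,
         suppression_violated = x$suppression_violated)
}
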
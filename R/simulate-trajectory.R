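#' Specify a synthetic treatment-response trajectory
#'
#' Emulates the longitudinal burden of a metastasis under phagocytic
#' clearance: exponential regression `burden0 * exp(-t / decay_tau)` while
#' clearance dominates, then exponential regrowth once clearance wanes
#' (after `regrowth_day`). Noise is multiplicative lognormal.
#'
#' @param burden0 Initial burden in mm^2.
#' @param decay_tau Decay time constant tau in days (> 0).
#' @param regrowth_day Day after which clearance ceases and the burden
#'   regrows; use `Inf` for pure decay.
#' @param regrowth_rate Exponential regrowth rate, per day.
#' @param sample_days Days at which the burden is recorded.
#' @param noise_gsd Geometric SD of multiplicative noise (>= 1). The default
#'   `exp(0.1)` corresponds to 10% multiplicative noise.
#' @param seed Integer seed.
#' @return An object of class `trajectory_spec`.
#' @seealso [simulate_trajectory()], [fit_decay()]
#' @export
trajectory_spec <- function(burden0 = 1,
                            decay_tau = 1.55,
                            regrowth_day = 10,
                            regrowth_rate = 0.3,
                            sample_days = 0:14,
                            noise_gsd = exp(0.1),
                            seed = 1L) {
  if (!is.numeric(decay_tau) || length(decay_tau) != 1 || decay_tau <= 0) {
    abort("`decay_tau` must be a single positive number of days.")
  }
  if (!is.numeric(burden0) || length(burden0) != 1 || burden0 <= 0) {
    abort("`burden0` must be a single positive burden (mm^2).")
  }
  if (!is.numeric(noise_gsd) || length(noise_gsd) != 1 || noise_gsd < 1) {
    abort("`noise_gsd` must be >= 1.")
  }
  if (!is.numeric(sample_days) || length(sample_days) < 1 ||
      any(sample_days < 0)) {
    abort("`sample_days` must be nonnegative days.")
  }
  structure(
    list(
      burden0 = burden0,
      decay_tau = decay_tau,
      regrowth_day = regrowth_day,
      regrowth_rate = regrowth_rate,
      sample_days = sort(as.numeric(sample_days)),
      noise_gsd = noise_gsd,
      seed = as.integer(seed)
    ),
    class = "trajectory_spec"
  )
}

#' Simulate a regression-then-regrowth burden trajectory
#'
#' @param spec A [trajectory_spec()].
#' @return A tibble with columns `day`, `burden_mm2` and
#'   `burden_true_mm2` (the noiseless curve).
#' @examples
#' simulate_trajectory(trajectory_spec(sample_days = 0:8, noise_gsd = 1))
#' @export
simulate_trajectory <- function(spec) {
  stopifnot(inherits(spec, "trajectory_spec"))
  t <- spec$sample_days
  decay_phase <- t <= spec$regrowth_day
  b_true <- numeric(length(t))
  b_true[decay_phase] <- spec$burden0 * exp(-t[decay_phase] / spec$decay_tau)
  if (any(!decay_phase)) {
    b_switch <- spec$burden0 * exp(-spec$regrowth_day / spec$decay_tau)
    b_true[!decay_phase] <-
      b_switch * exp(spec$regrowth_rate * (t[!decay_phase] - spec$regrowth_day))
  }
  with_seed(spec$seed, {
    noise <- rlnorm(length(t), meanlog = 0, sdlog = log(spec$noise_gsd))
    tibble(day = t, burden_mm2 = b_true * noise, burden_true_mm2 = b_true)
  })
}
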
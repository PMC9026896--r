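#' Specify a synthetic cross-sectional cohort
#'
#' A cohort emulates destructive sampling: each simulated mouse is measured
#' once, at its sacrifice day. Burden follows either a power law
#' `Area = A0 * t^B` or an exponential `Area = A0 * exp(k * t)`. Mouse-to-mouse
#' engraftment variability is lognormal around the median amplitude
#' (geometric SD `dispersion`), and measurement noise is multiplicative
#' lognormal (geometric SD `noise_gsd`), so burdens are never negative.
#'
#' @param group_label Label carried into the `group` column.
#' @param family `"power"` or `"exponential"`.
#' @param amplitude_median Median per-mouse amplitude A0, in mm^2.
#' @param dispersion Geometric SD of the per-mouse amplitude (>= 1; 1 = none).
#' @param exponent Power-law exponent B (unitless) or exponential rate k
#'   (per day), depending on `family`.
#' @param sacrifice_days Strictly positive sacrifice days.
#' @param mice_per_day Number of mice sacrificed at each day.
#' @param noise_gsd Geometric SD of multiplicative measurement noise (>= 1).
#' @param seed Integer seed; identical specs with identical seeds simulate
#'   bit-identical cohorts.
#'
#' @return An object of class `cohort_spec`.
#' @seealso [simulate_cohort()]
#' @export
cohort_spec <- function(group_label = "ctrl",
                        family = c("power", "exponential"),
                        amplitude_median = 0.0019,
                        dispersion = 1.6,
                        exponent = 4.1,
                        sacrifice_days = c(10, 12, 14, 16, 20),
                        mice_per_day = 10,
                        noise_gsd = 1.3,
                        seed = 1L) {
  family <- match.arg(family)
  if (!is.numeric(amplitude_median) || length(amplitude_median) != 1 ||
      amplitude_median <= 0) {
    abort("`amplitude_median` must be a single positive number (mm^2).")
  }
  if (!is.numeric(dispersion) || length(dispersion) != 1 || dispersion < 1) {
    abort("`dispersion` (geometric SD of amplitude) must be >= 1.")
  }
  if (!is.numeric(noise_gsd) || length(noise_gsd) != 1 || noise_gsd < 1) {
    abort("`noise_gsd` (geometric SD of measurement noise) must be >= 1.")
  }
  if (!is.numeric(sacrifice_days) || length(sacrifice_days) < 1 ||
      any(sacrifice_days <= 0)) {
    abort("`sacrifice_days` must all be strictly positive.")
  }
  if (!is.numeric(mice_per_day) || length(mice_per_day) != 1 ||
      mice_per_day < 1 || mice_per_day != round(mice_per_day)) {
    abort("`mice_per_day` must be a positive whole number.")
  }
  if (!is.numeric(exponent) || length(exponent) != 1) {
    abort("`exponent` must be a single number.")
  }
  structure(
    list(
      group_label = as.character(group_label),
      family = family,
      amplitude_median = amplitude_median,
      dispersion = dispersion,
      exponent = exponent,
      sacrifice_days = as.numeric(sacrifice_days),
      mice_per_day = as.integer(mice_per_day),
      noise_gsd = noise_gsd,
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

growth_factor <- function(family, exponent, day) {
  switch(family,
    power = day^exponent,
    exponential = exp(exponent * day)
  )
}

#' Simulate a cross-sectional burden cohort
#'
#' Draws `mice_per_day` mice per sacrifice day. Each mouse's area is
#' (lognormal amplitude) x (deterministic growth factor at its day) x
#' (lognormal measurement noise). The ground-truth per-mouse amplitude is
#' returned in the `amplitude_true` column.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with columns `mouse_id`, `group`, `day`, `area_mm2`,
#'   `nodule_count` (NA; filled by image quantification when available) and
#'   `amplitude_true`.
#' @examples
#' sim <- simulate_cohort(cohort_spec(seed = 7))
#' dplyr::count(sim, day)
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n_day <- spec$mice_per_day
  days <- rep(spec$sacrifice_days, each = n_day)
  n <- length(days)
  with_seed(spec$seed, {
    amp <- rlnorm(n, meanlog = log(spec$amplitude_median),
                  sdlog = log(spec$dispersion))
    noise <- rlnorm(n, meanlog = 0, sdlog = log(spec$noise_gsd))
    tibble(
      mouse_id = sprintf("%s_d%02d_m%02d", spec$group_label, days,
                         rep(seq_len(n_day), times = length(spec$sacrifice_days))),
      group = spec$group_label,
      day = days,
      area_mm2 = amp * growth_factor(spec$family, spec$exponent, days) * noise,
      nodule_count = NA_integer_,
      amplitude_true = amp
    )
  })
}
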
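---
title: "Tumor burden kinetics: quantification, calibration and projected survival"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tumor burden kinetics: quantification, calibration and projected survival}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lungburden)
library(dplyr)
```

## The problem

B16F10 melanoma cells injected into the tail vein of a mouse seed the lungs
with melanized metastatic nodules. Because the readout is destructive — each
mouse is sacrificed once, its lung lobes excised and photographed — growth
curves cannot be followed within an animal. Instead, a *cross-sectional*
cohort is assembled: groups of mice sacrificed at different days, each
contributing one burden measurement. `lungburden` implements the full
analysis chain for this design:

1. **Image quantification** — from lobe photographs to tumor area in mm².
2. **Growth calibration** — exponential and power-law fits across the cohort.
3. **Survival projection** — per-mouse extrapolation to a critical burden
   threshold, summarized as projected Kaplan–Meier curves compared by
   log-rank.
4. **Phagocytosis model** — a one-equation ODE coupling tumor growth to
   clearance by activated macrophages, and the decay-constant fit used for
   treatment-regression trajectories.
5. **Simulators** — seeded generators for cohorts, lobe images with known
   ground truth, and regression trajectories, so every stage is testable
   without animal data.

## Image quantification

Lobes are photographed against a printed 5 × 5 mm² grid, which fixes the
calibration: a grid square spanning 100 px per side gives
`mm_per_px = 0.05`, so one pixel covers `0.0025` mm². Only the **red
channel** is quantified — blood and bruising contaminate green and blue,
while melanin gives nodules a distinctively low red intensity.

Segmentation uses the Kapur **maximum-entropy threshold**: over the red
histogram restricted to the lobe selection, the threshold `t` maximizes the
sum of Shannon entropies of the two classes (levels `≤ t` and `> t`).
Numerical conventions, fixed once:

* natural logarithm; empty bins contribute zero (`0·ln 0 := 0`);
* 256 fixed bins, no histogram smoothing;
* candidate thresholds leaving either class empty are excluded;
* exact ties break toward the lowest qualifying level;
* a single-level (contrast-free) histogram has no threshold — quantification
  reports zero burden with a `degenerate` flag rather than guessing.

**Which class is tumor?** Melanized nodules are physically dark in red, so
the at-or-below-threshold class is assigned to tumor by default. (Binary
renderings in interactive tools often display the thresholded class as
white, which can suggest the opposite convention; the physical criterion is
what matters.) For non-melanized tumors that segment bright,
`quantify_lobe(..., tumor_dark = FALSE)` flips the convention.

Nodules are counted as 8-connected components of the tumor mask with at
least `min_px = 5` pixels; the floor removes single-pixel segmentation
specks and is configurable.

```{r image}
sim <- simulate_lobe_image(image_spec(seed = 3, pixel_noise_sd = 0))
quantify_lobe(sim$image)
sim$truth$tumor_fraction
```

## Growth calibration

Two growth laws describe lung burden versus days post-inoculation:

* power law: `Area = A0 · t^B`
* exponential: `Area = A0 · e^(k·t)`

Both are fit by **ordinary least squares in log coordinates**
(`ln Area ~ ln t` and `ln Area ~ t`). This choice matches the multiplicative
error structure of the data — engraftment differences and measurement noise
both act as factors, not offsets — and differs from untransformed nonlinear
least squares, which would let the largest burdens dominate. Zero-area
records have no logarithm; they are excluded and counted
(`n_zero_excluded`), with an optional positive floor (`floor_mm2`) for
sensitivity analysis. Each record is one independent mouse; there are no
repeated measures to model.

The calibrated reference parameters shipped in `reference_growth_fits()`
are: untreated power law `A0 = 0.0019` mm², `B = 4.1`; anti-Tyrp1-treated
power law `A0 = 0.0087` mm², `B = 3.0`; untreated exponential
`A0 = 0.05` mm², `k = 0.45`/day. Both families describe the same cohorts
acceptably and the package deliberately computes both without adjudicating
between them.

Derived kinetics follow in closed form: the exponential doubling time is
`ln 2 / k` (≈ 1.54 days at `k = 0.45`); power-law growth decelerates, with
doubling time `t(S)·(2^(1/B) − 1)` at burden `S` (≈ 2.6 days at 100 mm² for
the untreated fit). The treated-to-control prediction ratio
(`suppression_fold()`) reaches ≈ 4.6 at day 16.

```{r growth}
refs <- reference_growth_fits()
suppression_fold(refs$power_untreated, refs$power_treated, 16)
doubling_time(refs$power_untreated, at_area = 100)
```

### Variance–mean scaling

If mice differ by a multiplicative engraftment factor and then grow
deterministically, the coefficient of variation of burden is constant over
time, so the SD of a cohort cell scales linearly with its mean:
`log SD` versus `log mean` has slope 1. `variance_mean_scaling()` computes
this slope across (group, day) cells. Slope 1 supports exponential-type
growth seeded by early engraftment differences; slope 0.5 would instead
suggest counting-type noise.

## Survival projection from a single timepoint

The projection procedure turns one burden measurement per mouse into a
projected survival time:

1. Calibrate the growth exponent (`B` or `k`) on a multi-timepoint
   reference cohort, then **freeze** it. Per-mouse exponent refitting is
   not allowed — one measurement cannot constrain two parameters.
2. For each mouse measured at area `a` on day `d`, solve for the amplitude:
   `A0ᵢ = a/d^B` (power) or `a·e^(−k·d)` (exponential). The amplitude
   absorbs individual engraftment differences.
3. The projected survival time is the day the mouse's curve crosses the
   critical burden threshold, 300 mm² by default:
   `(300/A0ᵢ)^(1/B)` or `ln(300/A0ᵢ)/k`.

Projected times feed a Kaplan–Meier product-limit curve and a Mantel–Cox
log-rank comparison (two-sided, chi-square with 1 df; a single comparison
per experiment, so no multiplicity correction). Projection defaults to the
power family, which is the family used for the projected survival curves;
both families are supported.

Edge cases, decided here because the procedure itself is silent on them:

* **Zero-area mice** have no estimable curve; they are excluded from
  projection and enter the KM analysis right-censored at their measurement
  day.
* **Mice already above threshold** get a crossing day before their
  measurement day. A projected death cannot predate an observed survival,
  so their KM event time is their measurement day; the row is flagged
  (`above_threshold`).
* All other projected mice have fully determined event times, so the
  projected curves carry no censoring.

```{r projection}
cfg <- projection_config("power", exponent = 4.1, threshold_mm2 = 300)
cohort <- simulate_cohort(cohort_spec(seed = 8)) |> filter(day == 14)
proj <- project_cohort(cohort, cfg)
glance(proj)
```

## Growth versus phagocytosis

Tumor burden `B` under phagocytic attack follows

`dB/dt = (g − φ·max(P − P₀, 0)) · B`

where `g` is the intrinsic proliferation rate (per day), `P` the density of
phagocytic macrophages, `P₀` the inactivated baseline density, and `φ` the
clearance efficiency per unit density. The linear suppression term is the
minimal form consistent with growth being suppressed by phagocytes in
proportion to their activated excess; the rectification at `P = P₀` keeps a
phagocyte *deficit* from spuriously boosting growth. With `P` fixed (a
snapshot covariate, not a dynamic population), the solution is a pure
exponential in the net rate, so growth, stasis and regression are all
reachable by the sign of `g − φ(P − P₀)`.

Two fits accompany the model:

* `fit_decay()` extracts the clearance time constant `τ = −1/slope` from
  `ln B` versus `t` in a regression-phase window (default 0–8 days,
  before regrowth resumes; the treated reference trajectory decays as
  `exp(−t/1.55)`).
* `fit_burden_vs_phagocytes()` fits the cross-sectional snapshot
  `ln B = c₀ − c₁(P − P₀)`. Only the product `φ·P` is identifiable from
  burden data, so `c₁` is reported as a suppression coefficient, not `φ`
  itself; a positive burden–density association raises an explicit
  `suppression_violated` flag.

## What the simulators emulate — and what they do not

`simulate_cohort()` draws a per-mouse amplitude from a lognormal with the
stated median and geometric SD (`dispersion`), multiplies by the
deterministic growth factor at the sacrifice day, and applies lognormal
measurement noise. Lognormal amplitude is the minimal multiplicative model
consistent with constant-CV variance scaling; burdens can never go
negative. The magnitudes of engraftment spread (geometric SD 1.6) and
measurement noise (geometric SD 1.3) are package defaults chosen as
realistic for surface-area quantification of engrafted cohorts — they are
not published values.

`simulate_lobe_image()` paints an elliptical lobe with circular,
constant-intensity dark nodules and clutter in the non-red channels.
Texture, specular highlights, bruising gradients and irregular nodule
shapes are out of scope, so passing image tests demonstrates correctness of
the thresholding arithmetic, not robustness to real photographic artifacts.

`simulate_trajectory()` produces exponential decay with time constant
`decay_tau` followed by exponential regrowth after `regrowth_day`
(default day 10, when clearance wanes; default regrowth rate 0.3/day,
chosen slower than untreated growth because clearance persists partially).

Problem sizes used in the shipped tests: 20 cohorts of 50 mice for
power-law recovery, 50 nine-point trajectories for decay recovery, and
4000 mice/day across six days for the variance-scaling slope, where the
±0.01 band demands small sampling error.

## Known limitations

* Growth families are limited to exponential and power law; Gompertz or
  logistic alternatives, and formal model selection between families, are
  out of scope.
* The projection yields point curves only — no confidence bands — and
  inherits the frozen-exponent assumption.
* The phagocytosis model treats `P` as constant; predator–prey style
  feedback of tumor burden on macrophage numbers is not modeled.
* Interactive lobe selection is not provided; masks are supplied or
  simulated.
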
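# lungburden

Quantitative analysis of lung-metastasis burden for preclinical
immunotherapy studies built on destructive (cross-sectional) sampling:
each mouse is sacrificed once, its lung lobes photographed, and growth
kinetics must be calibrated *across* animals rather than within them.
The package targets B16F10 melanoma lung metastases — melanized, hence
optically dark nodules — treated by macrophage-checkpoint approaches
(CD47 knockout plus tumor-opsonizing anti-Tyrp1), but every component is
parameterized and reusable.

It provides, as composable data-frame-first functions:

* **Image quantification** (`quantify_lobe()`): red-channel extraction,
  Kapur maximum-entropy auto-thresholding, conversion to mm² via a printed
  5 × 5 mm² grid calibration, and 8-connectivity nodule counting.
* **Growth calibration** (`fit_growth()`): power-law `Area = A0·t^B` and
  exponential `Area = A0·e^(k·t)` fits by least squares in log coordinates,
  with doubling times, suppression folds between treatment arms, and
  variance–mean (Taylor-law) scaling of cohort burdens.
* **Survival projection** (`project_cohort()`, `build_km()`,
  `logrank_test()`): a frozen cohort-calibrated exponent plus one burden
  measurement per mouse yields a per-mouse amplitude and the projected day
  its burden crosses a critical threshold (default 300 mm²); projected
  times feed Kaplan–Meier curves compared by Mantel–Cox log-rank.
* **Phagocytosis model** (`solve_burden()`, `fit_decay()`,
  `fit_burden_vs_phagocytes()`): the ODE
  `dB/dt = (g − φ·max(P − P0, 0))·B` coupling tumor growth to clearance by
  activated macrophages, and the `exp(−t/τ)` decay fit for
  treatment-regression trajectories.
* **Seeded simulators** (`simulate_cohort()`, `simulate_lobe_image()`,
  `simulate_trajectory()`): generate every input with known ground truth.
* **Pipeline orchestration** (`run_pipeline()`): simulate → quantify → fit
  → project → compare from one config list or YAML file, with a manifest
  for bit-identical re-runs.

Fitted objects follow broom conventions (`tidy()`, `glance()`) and result
types have `autoplot()` methods.

## Worked example

Simulate an untreated cohort at the calibrated reference parameters
(`A0 = 0.0019` mm², `B = 4.1`, engraftment geometric SD 1.6, measurement
noise geometric SD 1.3), refit the growth law, and project survival from
the day-14 mice:

```r
library(lungburden)
library(dplyr)

cohort <- simulate_cohort(cohort_spec(group_label = "ctrl", seed = 1))
fit <- fit_growth(cohort, "power")
fit
#> <growth_fit> Area = A0 * t^B
#>   A0 = 0.00259 mm^2, B = 4.012 (SE 0.275)
#>   n = 50 records
```

The recovered exponent (4.01 ± 0.28) matches the generating value 4.1
within its standard error: fifty cross-sectional measurements calibrate
the growth law without any longitudinal imaging. The reference fits for
the two treatment arms imply the treated/control burden ratio at day 16:

```r
refs <- reference_growth_fits()
suppression_fold(refs$power_untreated, refs$power_treated, 16)
#> [1] 4.610694
```

i.e. anti-Tyrp1 suppresses burden ~4.6-fold at sacrifice. Projection then
turns each day-14 measurement into a threshold-crossing day:

```r
proj <- cohort |>
  filter(day == 14) |>
  project_cohort(projection_config("power", exponent = fit$exponent))
glance(proj)
#> # A tibble: 1 × 7
#>       n n_zero_area n_above_threshold median_crossing_day family exponent
#>   <int>       <int>             <int>               <dbl> <chr>     <dbl>
#> 1    10           0                 0                18.6 power      4.01
km <- build_km(proj$km_time, proj$km_event)
km
#> <km_curve> n = 10, 10 event time(s), median = 18.45186 days
```

A projected median survival of ~18.5 days for untreated mice measured on
day 14, consistent with the closed-form crossing of the reference curves
(300 mm² is reached near day 19–20). Image quantification recovers a
simulated lobe's ground truth:

```r
sim <- simulate_lobe_image(image_spec(seed = 3))
quantify_lobe(sim$image)
#> # A tibble: 1 × 6
#>   tumor_fraction tumor_area_mm2 lobe_area_mm2 threshold_level nodule_count
#>            <dbl>          <dbl>         <dbl>           <int>        <int>
#> 1         0.0612           2.60          42.5             150            8
sim$truth$tumor_fraction
#> [1] 0.05322657
```

The thresholded tumor fraction (6.1%) tracks the painted ground truth
(5.3%); the gap is the expected cost of pixel noise at this contrast, and
all 8 painted nodules are found.

See `vignettes/burden-kinetics.Rmd` for the models, assumptions and design
decisions in full.

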
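test_that("single-mouse projection matches the closed forms", {
  # already at threshold: crossing equals the measurement day
  for (fam in c("power", "exponential")) {
    cfg <- projection_config(fam, exponent = if (fam == "power") 4.1 else 0.45)
    pm <- project_mouse(300, 14, cfg)
    expect_equal(pm$crossing_day, 14, tolerance = 1e-12)
    expect_true(pm$above_threshold)
  }
  # exponential: k = 0.45, 50 mm^2 at day 14 -> A0 ~ 0.0918, crossing ~ 18.0
  pm_exp <- project_mouse(50, 14, projection_config("exponential", 0.45))
  expect_equal(pm_exp$amplitude_i, 50 * exp(-0.45 * 14), tolerance = 1e-12)
  expect_equal(pm_exp$amplitude_i, 0.0918, tolerance = 1e-3)
  expect_equal(pm_exp$crossing_day, log(300 / (50 * exp(-0.45 * 14))) / 0.45,
               tolerance = 1e-12)
  expect_equal(pm_exp$crossing_day, 18.0, tolerance = 1e-2)
  # power: B = 4.1, 95.2 mm^2 at day 14 -> A0 ~ 0.0019, crossing ~ 18.5
  pm_pow <- project_mouse(95.2, 14, projection_config("power", 4.1))
  expect_equal(pm_pow$amplitude_i, 95.2 / 14^4.1, tolerance = 1e-12)
  expect_equal(pm_pow$amplitude_i, 0.0019, tolerance = 2e-3)
  expect_equal(pm_pow$crossing_day, 18.5, tolerance = 0.05)
})

test_that("projection round-trips through the growth law at the threshold", {
  set.seed(4)
  for (i in 1:50) {
    fam <- sample(c("power", "exponential"), 1)
    ex <- runif(1, 0.2, 5)
    thr <- runif(1, 100, 500)
    cfg <- projection_config(fam, ex, thr)
    area <- runif(1, 0.5, 250)
    day <- runif(1, 5, 20)
    pm <- project_mouse(area, day, cfg)
    fwd <- predict_area(growth_fit(fam, pm$amplitude_i, ex), pm$crossing_day)
    expect_equal(fwd, thr, tolerance = 1e-9)
  }
})

test_that("cohort projection handles flags, monotonicity and the median", {
  cfg <- projection_config("power", 4.1)
  same <- tibble::tibble(mouse_id = letters[1:4], area_mm2 = 50, day = 14)
  pr <- project_cohort(same, cfg)
  expect_equal(length(unique(pr$crossing_day)), 1L)
  expect_equal(glance(pr)$median_crossing_day, pr$crossing_day[1])
  # larger burden at a fixed day projects strictly earlier crossing
  grad <- tibble::tibble(mouse_id = letters[1:5],
                         area_mm2 = c(5, 20, 80, 150, 290), day = 14)
  pg <- project_cohort(grad, cfg)
  expect_true(all(diff(pg$crossing_day) < 0))
  # zero-area mice are censored at their measurement day
  with_zero <- tibble::tibble(mouse_id = c("a", "b"), area_mm2 = c(0, 50), day = 14)
  pz <- project_cohort(with_zero, cfg)
  expect_true(pz$zero_area[1])
  expect_false(pz$km_event[1])
  expect_equal(pz$km_time[1], 14)
  # above-threshold mice get their measurement day as the KM event time
  hot <- tibble::tibble(mouse_id = "x", area_mm2 = 400, day = 14)
  ph <- project_cohort(hot, cfg)
  expect_true(ph$above_threshold)
  expect_lt(ph$crossing_day, 14)
  expect_equal(ph$km_time, 14)
  expect_true(ph$km_event)
  expect_error(project_cohort(dplyr::bind_rows(hot, hot), cfg), "duplicated")
})

test_that("a cohort lying exactly on the reference exponential projects one crossing day", {
  refs <- reference_growth_fits()
  days <- c(10, 12, 14, 16)
  records <- tibble::tibble(
    mouse_id = paste0("m", seq_along(days)),
    area_mm2 = predict_area(refs$exponential_untreated, days),
    day = days
  )
  pr <- project_cohort(records, projection_config("exponential", 0.45))
  closed_form <- log(300 / 0.05) / 0.45
  expect_equal(pr$crossing_day, rep(closed_form, 4), tolerance = 1e-10)
  expect_true(closed_form > 19 && closed_form < 20)
})

test_that("KM curve matches closed forms with and without censoring", {
  km <- build_km(c(18, 19, 20, 21, 22))
  expect_equal(km$survival, c(0.8, 0.6, 0.4, 0.2, 0))
  expect_equal(km_median(km), 20)
  # all censored: survival never drops
  kc <- build_km(c(5, 8, 12), events = c(FALSE, FALSE, FALSE))
  expect_true(all(kc$survival == 1))
  expect_true(is.na(km_median(kc)))
  # one event among n drops S to (n-1)/n
  k1 <- build_km(c(3, 9, 9, 9), events = c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(k1$survival[1], 3 / 4)
  expect_error(build_km(numeric(0)), "nonempty")
})

test_that("KM without censoring equals the empirical survival function", {
  set.seed(10)
  for (i in 1:20) {
    times <- sample(1:15, sample(3:12, 1), replace = TRUE)
    km <- build_km(times)
    emp <- vapply(km$time, function(t) mean(times > t), numeric(1))
    expect_equal(km$survival, emp, tolerance = 1e-12)
  }
})

test_that("log-rank matches hand computation, symmetry and null cases", {
  lr <- logrank_test(c(1, 2), c(3, 4))
  expect_equal(lr$statistic, 49 / 17, tolerance = 1e-12)  # (2 - 5/6)^2 / (17/36)
  expect_equal(lr$observed_a, 2)
  expect_equal(lr$expected_a, 5 / 6, tolerance = 1e-12)
  # identical groups: O = E at every event time
  expect_equal(logrank_test(c(2, 5, 9), c(2, 5, 9))$statistic, 0)
  # label swap leaves the statistic unchanged
  set.seed(2)
  ta <- sample(1:20, 6); tb <- sample(1:20, 9)
  expect_equal(logrank_test(ta, tb)$statistic,
               logrank_test(tb, ta)$statistic, tolerance = 1e-12)
  # no events anywhere
  none <- logrank_test(c(1, 2), c(3, 4),
                       events_a = c(FALSE, FALSE), events_b = c(FALSE, FALSE))
  expect_equal(none$statistic, 0)
  expect_equal(none$p_value, 1)
})

test_that("log-rank and KM agree with the survival package on random data", {
  skip_if_not_installed("survival")
  set.seed(17)
  for (i in 1:100) {
    na <- sample(3:10, 1); nb <- sample(3:10, 1)
    ta <- sample(1:25, na, replace = TRUE)
    tb <- sample(1:25, nb, replace = TRUE)
    ea <- runif(na) < 0.8
    eb <- runif(nb) < 0.8
    if (!any(ea) && !any(eb)) next
    ours <- logrank_test(ta, tb, ea, eb)
    ref <- survival::survdiff(
      survival::Surv(c(ta, tb), c(ea, eb)) ~ rep(c("a", "b"), c(na, nb))
    )
    expect_equal(ours$statistic, ref$chisq, tolerance = 1e-6)
  }
  # KM against survfit on one uncensored and one censored dataset
  tt <- c(4, 4, 7, 9, 12, 12, 15); ee <- c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE)
  km <- build_km(tt, ee)
  sf <- survival::survfit(survival::Surv(tt, ee) ~ 1)
  expect_equal(km$survival, sf$surv, tolerance = 1e-12)
})

test_that("projected survival separates treated from untreated cohorts", {
  # cohorts simulated at the two reference power laws, measured at day 14;
  # projections should order treated above untreated nearly always
  cfg_ct <- projection_config("power", 4.1)
  cfg_tx <- projection_config("power", 3.0)
  wins <- 0L
  n_rep <- 100
  for (s in seq_len(n_rep)) {
    ctrl <- simulate_cohort(cohort_spec(
      "ctrl", "power", amplitude_median = 0.0019, exponent = 4.1,
      sacrifice_days = 14, mice_per_day = 10, seed = 1000 + s
    ))
    tx <- simulate_cohort(cohort_spec(
      "tx", "power", amplitude_median = 0.0087, exponent = 3.0,
      sacrifice_days = 14, mice_per_day = 10, seed = 5000 + s
    ))
    med_ct <- glance(project_cohort(ctrl, cfg_ct))$median_crossing_day
    med_tx <- glance(project_cohort(tx, cfg_tx))$median_crossing_day
    wins <- wins + (med_tx > med_ct)
  }
  expect_gte(wins / n_rep, 0.95)
})

test_that("projected group comparison runs end to end", {
  ctrl <- simulate_cohort(cohort_spec(
    "ctrl", "power", amplitude_median = 0.0019, exponent = 4.1,
    sacrifice_days = 14, mice_per_day = 10, seed = 31
  ))
  tx <- simulate_cohort(cohort_spec(
    "tx", "power", amplitude_median = 0.0087, exponent = 3.0,
    sacrifice_days = 14, mice_per_day = 10, seed = 32
  ))
  pa <- project_cohort(ctrl, projection_config("power", 4.1))
  pb <- project_cohort(tx, projection_config("power", 3.0))
  lr <- compare_projected_survival(pa, pb)
  expect_s3_class(lr, "logrank_test")
  expect_true(lr$p_value >= 0 && lr$p_value <= 1)
  td <- tidy(lr)
  expect_equal(td$statistic, lr$statistic)
})
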
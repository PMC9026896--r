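test_that("red channel extraction is an untouched slice of channel 1", {
  px <- array(0, dim = c(4, 5, 3))
  px[, , 1] <- matrix(sample(0:255, 20), 4, 5)
  px[, , 2] <- 7; px[, , 3] <- 200
  expect_identical(red_channel(px), px[, , 1])
  pure_red <- array(rep(c(255, 0, 0), each = 6), dim = c(2, 3, 3))
  expect_true(all(red_channel(pure_red) == 255))
  pure_blue <- array(rep(c(0, 0, 255), each = 6), dim = c(2, 3, 3))
  expect_true(all(red_channel(pure_blue) == 0))
  expect_error(red_channel(matrix(1, 3, 3)), "3-channel")
})

test_that("max-entropy threshold handles degenerate and two-delta histograms", {
  h1 <- numeric(256); h1[101] <- 1000  # single occupied level
  expect_error(kapur_threshold(h1), "no threshold")
  h2 <- numeric(256); h2[c(51, 201)] <- 500  # levels 50 and 200, equal mass
  # every split between the deltas attains entropy 0; lowest tie wins
  expect_identical(kapur_threshold(h2), 50L)
})

test_that("max-entropy threshold separates a bimodal mixture sensibly", {
  set.seed(21)
  vals <- c(round(rnorm(5000, 60, 10)), round(rnorm(5000, 180, 10)))
  vals <- pmin(pmax(vals, 0), 255)
  h <- tabulate(vals + 1, nbins = 256)
  t_est <- kapur_threshold(h)
  expect_gt(t_est, 80)
  expect_lt(t_est, 160)
  expect_identical(t_est, oracle_max_entropy(h))
})

test_that("max-entropy threshold matches the exhaustive oracle on random histograms", {
  set.seed(7)
  for (i in 1:200) {
    h <- random_histogram()
    expect_identical(kapur_threshold(h), oracle_max_entropy(h))
  }
})

test_that("threshold depends on the histogram only (pixel permutation invariant)", {
  set.seed(12)
  vals <- sample(c(30:60, 150:200), 400, replace = TRUE)
  m1 <- matrix(vals, 20, 20)
  m2 <- matrix(sample(vals), 20, 20)
  expect_identical(kapur_threshold(m1), kapur_threshold(m2))
})

test_that("component labeling agrees with a region-growing oracle", {
  set.seed(33)
  for (i in 1:20) {
    mask <- matrix(runif(15 * 18) < 0.35, 15, 18)
    expect_equal(max(label_components(mask)), oracle_count_components(mask))
    expect_equal(count_nodules(mask, min_px = 3),
                 oracle_count_components(mask, min_px = 3))
  }
})

test_that("nodule counting follows 8-connectivity and the size filter", {
  expect_equal(count_nodules(matrix(FALSE, 5, 5)), 0L)
  two <- matrix(FALSE, 12, 20)
  two[3:6, 3:6] <- TRUE
  two[8:11, 14:17] <- TRUE
  expect_equal(count_nodules(two, min_px = 5), 2L)
  # two squares touching only at one diagonal corner merge under 8-connectivity
  diag_touch <- matrix(FALSE, 10, 10)
  diag_touch[2:4, 2:4] <- TRUE
  diag_touch[5:7, 5:7] <- TRUE
  expect_equal(count_nodules(diag_touch, min_px = 1), 1L)
  expect_equal(oracle_count_components(diag_touch), 1L)
  # single-pixel specks drop below min_px
  speck <- matrix(FALSE, 6, 6); speck[2, 2] <- TRUE
  expect_equal(count_nodules(speck, min_px = 5), 0L)
  expect_equal(count_nodules(speck, min_px = 1), 1L)
})

test_that("quantification recovers the painted tumor fraction at high contrast", {
  sim <- simulate_lobe_image(image_spec(
    seed = 2, pixel_noise_sd = 0, nodule_red_level = 40, lung_red_level = 160
  ))
  q <- quantify_lobe(sim$image)
  expect_false(q$degenerate)
  expect_equal(q$tumor_fraction, sim$truth$tumor_fraction, tolerance = 0.02)
  expect_equal(q$nodule_count, sim$truth$nodule_count)
  expect_equal(q$tumor_area_mm2 / q$lobe_area_mm2, q$tumor_fraction)
  expect_lte(q$tumor_area_mm2, q$lobe_area_mm2)
  # tumor + normal fractions partition the lobe
  expect_equal(q$tumor_fraction + (1 - q$tumor_fraction), 1)
})

test_that("grid calibration converts pixel counts to mm^2", {
  # a 5 mm grid square spanning 100 px per side -> 0.05 mm/px,
  # so a 400-px nodule covers 1.0 mm^2
  sim <- simulate_lobe_image(image_spec(seed = 2, pixel_noise_sd = 0,
                                        mm_per_px = 0.05))
  q <- quantify_lobe(sim$image)
  tumor_px <- round(q$tumor_area_mm2 / 0.05^2)
  expect_equal(q$tumor_area_mm2, tumor_px * 0.05^2)
  expect_equal(400 * 0.05^2, 1.0)
})

test_that("blue/green clutter never changes quantification", {
  sim <- simulate_lobe_image(image_spec(seed = 9))
  img <- sim$image
  q1 <- quantify_lobe(img)
  set.seed(1)
  img2 <- img
  img2$pixels[, , 2] <- sample(0:255, length(img$pixels[, , 2]), replace = TRUE)
  img2$pixels[, , 3] <- 0
  expect_identical(quantify_lobe(img2), q1)
})

test_that("a contrast-free lobe reports zero burden with a degenerate flag", {
  px <- array(0, dim = c(20, 20, 3))
  px[, , 1] <- 160
  img <- lobe_image(px, mm_per_px = 0.05)
  expect_warning(q <- quantify_lobe(img), "degenerate")
  expect_equal(q$tumor_area_mm2, 0)
  expect_true(q$degenerate)
})

test_that("tumor-is-light convention flips the selected class", {
  px <- array(0, dim = c(10, 10, 3))
  red <- matrix(40, 10, 10); red[1:5, ] <- 160
  px[, , 1] <- red
  img <- lobe_image(px, mm_per_px = 0.1)
  dark <- quantify_lobe(img, tumor_dark = TRUE)
  light <- quantify_lobe(img, tumor_dark = FALSE)
  expect_equal(dark$tumor_fraction + light$tumor_fraction, 1)
})

test_that("PNG round trip preserves pixels and quantification", {
  sim <- simulate_lobe_image(image_spec(seed = 14))
  path <- withr::local_tempfile(fileext = ".png")
  write_lobe_png(sim$image, path)
  back <- read_lobe_png(path, mm_per_px = sim$image$mm_per_px)
  expect_equal(back$pixels[, , 1], sim$image$pixels[, , 1])
  q_mem <- quantify_lobe(sim$image)
  img_back <- lobe_image(back$pixels, sim$image$mm_per_px, sim$image$lobe_mask)
  expect_equal(quantify_lobe(img_back), q_mem)
})
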
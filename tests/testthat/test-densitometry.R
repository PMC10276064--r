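test_that("gray-to-absorbance follows Beer-Lambert with clamping", {
  expect_equal(gray_to_absorbance(200, 200), 0)
  expect_equal(gray_to_absorbance(20, 200), 1)
  expect_equal(gray_to_absorbance(63.2, 200), 0.500, tolerance = 1e-3)
  # intensities above background clamp to OD 0
  expect_equal(gray_to_absorbance(210, 200), 0)
  expect_error(gray_to_absorbance(0, 200), "positive")
  expect_error(gray_to_absorbance(100, -1), "positive")
})

test_that("gray -> OD -> gray round trip is the identity within 1 gray level", {
  for (i in c(1, 5, 20, 63, 127, 199)) {
    od <- gray_to_absorbance(i, 200)
    back <- myosectr:::absorbance_to_gray(od, 200)
    expect_lt(abs(back - i), 1)
  }
})

test_that("calibration fit recovers constructed lines exactly", {
  conc <- c(0, 0.2, 0.4, 0.6, 0.8)
  exact <- tibble::tibble(concentration_mM = conc, absorbance = 1.0 * conc)
  cv <- fit_calibration(exact)
  expect_equal(cv$slope, 1.0, tolerance = 1e-12)
  expect_equal(cv$intercept, 0, tolerance = 1e-12)
  expect_equal(cv$r_squared, 1, tolerance = 1e-12)

  offset <- tibble::tibble(concentration_mM = conc,
                           absorbance = 0.9 * conc + 0.05)
  cv2 <- fit_calibration(offset)
  expect_equal(cv2$slope, 0.9, tolerance = 1e-12)
  expect_equal(cv2$intercept, 0.05, tolerance = 1e-12)

  expect_error(fit_calibration(
    tibble::tibble(concentration_mM = c(0.4, 0.4), absorbance = c(0.3, 0.5))),
    "distinct")
  expect_error(fit_calibration(
    tibble::tibble(concentration_mM = conc, absorbance = -conc)),
    "not positive")
})

test_that("a zero-noise section calibrates to the rendering extinction", {
  sec <- demo_section()
  std <- read_calibration_standards(sec)
  cv <- fit_calibration(std)
  expect_equal(cv$slope, sec$optics$extinction_scale, tolerance = 0.01)
  expect_lt(abs(cv$intercept), 0.01)
  expect_gt(cv$r_squared, 0.999)
  expect_equal(estimate_background(sec), 200)
})

test_that("capillary spot exclusion removes exactly the rendered spot pixels", {
  sec <- demo_section()
  cv <- fit_calibration(read_calibration_standards(sec))
  bg <- estimate_background(sec)
  lab <- sec$truth$label
  tr <- sec$channels$transmission
  spots <- sec$truth$spots
  fid <- spots$fiber_id[1]
  fiber_lin <- which(lab == fid)
  od <- gray_to_absorbance(pmax(tr[fiber_lin], 0.5), bg)
  ex <- exclude_capillary_spots(od, cv)
  truth_spot <- sort(unlist(spots$pixels[spots$fiber_id == fid]))
  expect_identical(sort(fiber_lin[!ex$include]), truth_spot)

  # no pixel above threshold: all-inclusive mask
  ex0 <- exclude_capillary_spots(c(0.1, 0.4, 0.7), cv)
  expect_true(all(ex0$include))
  expect_equal(ex0$n_excluded, 0)

  # fiber fully covered by spot: measurement failure
  expect_error(exclude_capillary_spots(rep(5, 10), cv), "unusable")
})

test_that("per-fiber concentration round-trips the rendered ground truth", {
  sec <- demo_section()
  res <- measure_section_mb(sec)
  truth <- sec$truth$fibers
  joined <- dplyr::left_join(res$measurements, truth, by = "fiber_id")
  rel_err <- abs(joined$concentration_mM - joined$mb_mM) / joined$mb_mM
  # bounded by half-a-gray-level quantization at each fiber's intensity
  expect_lt(max(rel_err), 0.02)
  expect_lt(median(rel_err), 0.01)

  # mean OD at the intercept maps to 0 mM
  cv <- res$curve
  m0 <- fiber_mb_concentration(rep(cv$intercept, 5), cv, fiber_id = 1L)
  expect_equal(m0$concentration_mM, 0)

  # monotonicity: higher true OD never yields lower concentration
  ods <- seq(0.05, 0.75, by = 0.05)
  conc <- vapply(ods, function(o)
    fiber_mb_concentration(rep(o, 10), cv)$concentration_mM, numeric(1))
  expect_true(all(diff(conc) > 0))
})

test_that("fiber-type-weighted Mb matches the closed form and its bounds", {
  expect_equal(weighted_average_mb(0.5, 0.5, 37), 0.5)
  expect_equal(weighted_average_mb(0.41, 0.33, 66), 0.3828)
  expect_equal(weighted_average_mb(0.41, 0.33, 100), 0.41)
  expect_equal(weighted_average_mb(0.41, 0.33, 0), 0.33)
  expect_error(weighted_average_mb(0.4, 0.3, 120), "0, 100")
  # weighted mean always lies between the two type concentrations
  withr::with_seed(5, {
    for (k in 1:200) {
      m1 <- runif(1, 0.1, 0.9); m2 <- runif(1, 0.1, 0.9)
      p <- runif(1, 0, 100)
      w <- weighted_average_mb(m1, m2, p)
      expect_gte(w, min(m1, m2) - 1e-12)
      expect_lte(w, max(m1, m2) + 1e-12)
    }
  })
})
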
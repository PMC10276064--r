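test_that("fragment classification implements the positional/Pax7 rules", {
  fr <- tibble::tibble(
    touches_basal_lamina = c(TRUE, TRUE, FALSE, TRUE, FALSE),
    inside_fiber = c(TRUE, TRUE, TRUE, FALSE, FALSE),
    pax7_positive = c(FALSE, TRUE, FALSE, FALSE, FALSE)
  )
  cl <- classify_fragments(fr)
  expect_equal(cl$assigned_class,
               c("myonucleus", "satellite", "central",
                 "interstitial", "interstitial"))
  expect_error(classify_fragments(tibble::tibble(
    touches_basal_lamina = NA, inside_fiber = TRUE, pax7_positive = FALSE)),
    "NA")
})

test_that("correction factor counts the sections a nucleus appears in", {
  expect_identical(correction_factor(11, 10, 1), 2L)
  expect_identical(correction_factor(9, 10, 1), 1L)
  expect_identical(correction_factor(21, 10, 1), 3L)
  expect_error(correction_factor(1, 10, 1), "exceed")
  expect_error(correction_factor(11, -1, 1), "> 0")
})

test_that("nuclei per mm and domain size follow the stereology formulas", {
  expect_equal(nuclei_per_mm(4.34, 1000, 10, 2), 217.0)
  expect_equal(nuclei_per_mm(4.30, 1000, 10, 2), 215.0)
  # doubling the correction factor halves the linear density
  expect_equal(nuclei_per_mm(4.34, 1000, 10, 4),
               nuclei_per_mm(4.34, 1000, 10, 2) / 2)

  expect_equal(mds(6556, 217), 30.2, tolerance = 1e-2)
  expect_equal(mds(6824, 215), 31.7, tolerance = 1e-2)
  expect_equal(mds(2 * 6556, 217), 2 * mds(6556, 217))
  expect_error(mds(6556, 0), "> 0")

  # MDS decreases in the fragment count and increases in F at fixed FCSA
  counts <- seq(2, 8, by = 0.5)
  m <- mds(6556, nuclei_per_mm(counts))
  expect_true(all(diff(m) < 0))
  f_vals <- 1:4
  m_f <- mds(6556, nuclei_per_mm(4.34, f = f_vals))
  expect_true(all(diff(m_f) > 0))
})

test_that("satellite fraction formula and its edge cases", {
  expect_equal(satellite_fraction(0, 4.3), 0)
  expect_equal(satellite_fraction(0.13, 4.34), 2.91, tolerance = 1e-2)
  expect_equal(satellite_fraction(0.15, 4.30), 3.37, tolerance = 1e-2)
  expect_error(satellite_fraction(0, 0), "Zero total")
  expect_error(satellite_fraction(-0.1, 4), ">= 0")
})

test_that("zero-noise fragment detection reproduces truth classes exactly", {
  sec <- demo_section()
  det <- detect_fragments(sec)
  truth <- sec$truth$fragments
  expect_equal(nrow(det), nrow(truth))
  m <- match_fragments(truth, det)
  expect_true(all(m$matched))
  # confusion matrix is diagonal
  expect_equal(m$detected_class, m$truth_class)
})

test_that("stereology counts myonuclei only, in circularity-passing fibers", {
  sec <- demo_section()
  morpho <- measure_morphometry(sec)
  det <- detect_fragments(sec)
  st <- measure_stereology(sec, morpho = morpho, fragments = det)
  counted <- morpho$fiber_id[morpho$included]
  truth <- sec$truth$fragments

  # the measured per-fiber myonuclear count equals the truth count
  # over the same (included) fiber set
  truth_nmf <- mean(vapply(counted, function(i) {
    sum(truth$fiber_id == i & truth$class == "myonucleus", na.rm = TRUE)
  }, numeric(1)))
  expect_equal(st$n_m_f, truth_nmf)
  truth_sat <- mean(vapply(counted, function(i) {
    sum(truth$fiber_id == i & truth$class == "satellite", na.rm = TRUE)
  }, numeric(1)))
  expect_equal(st$satellites_per_fiber, truth_sat)

  # satellites/central/interstitial never enter N_m,f: totals bound it
  expect_lte(st$n_m_f * length(counted),
             sum(truth$class == "myonucleus"))

  # N_m,l and MDS are consistent with their defining formulas
  expect_equal(st$n_m_l, nuclei_per_mm(st$n_m_f))
  expect_equal(st$mds_pL, mds(st$mean_fcsa_um2, st$n_m_l))
  expect_equal(st$satellite_fraction_pct,
               satellite_fraction(st$satellites_per_fiber, st$n_m_f))
})

test_that("measured nuclear lengths feed the correction factor sensibly", {
  sec <- generate_longitudinal_section(c(11, 0), n_nuclei = 36, seed = 3)
  meas <- measure_nuclear_lengths(sec)
  f <- correction_factor(mean(meas$length_um), 10, 1)
  expect_identical(f, 2L)
})
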
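test_that("zero-absorbance fiber renders at the background intensity", {
  subj <- make_subject(mb1 = 0, mb2 = 0)
  opt <- zero_noise_optics(capillary_spot_density = 0)
  sec <- generate_section(subj, opt, n_fibers = 1, seed = 2, fiber_mb_cv = 0)
  lab <- sec$truth$label
  expect_true(all(sec$channels$transmission[lab == 1L] == 200))
})

test_that("fiber intensity follows Beer-Lambert exactly at zero noise", {
  subj <- make_subject(mb1 = 0.5, mb2 = 0.5, pct1 = 100)
  opt <- zero_noise_optics(capillary_spot_density = 0)
  sec <- generate_section(subj, opt, n_fibers = 1, seed = 2, fiber_mb_cv = 0)
  lab <- sec$truth$label
  # 200 * 10^-0.5 = 63.245..., quantized to 63
  expect_true(all(sec$channels$transmission[lab == 1L] == 63))
})

test_that("sections are bit-identical under a fixed seed", {
  subj <- make_subject()
  a <- generate_section(subj, optics_params(), n_fibers = 10, seed = 12)
  b <- generate_section(subj, optics_params(), n_fibers = 10, seed = 12)
  c <- generate_section(subj, optics_params(), n_fibers = 10, seed = 13)
  expect_identical(a$channels, b$channels)
  expect_identical(a$truth$fibers, b$truth$fibers)
  expect_identical(a$truth$fragments, b$truth$fragments)
  expect_false(identical(a$channels, c$channels))
})

test_that("truth labels and rendered channels are mutually consistent", {
  sec <- demo_section()
  fr <- sec$truth$fragments
  expect_gt(nrow(fr), 0)
  # every truth fragment has a DAPI blob at its centre
  dapi_at <- sec$channels$dapi[cbind(fr$row, fr$col)]
  expect_true(all(dapi_at > 128))
  # every Pax7+ truth fragment has a Pax7 blob; Pax7- fragments do not
  pax_at <- sec$channels$pax7[cbind(fr$row, fr$col)]
  expect_true(all(pax_at[fr$pax7_positive] > 128))
  expect_true(all(pax_at[!fr$pax7_positive] < 128))
  # fiber label map is consistent with the MHC channels
  lab <- sec$truth$label
  for (i in sec$truth$fibers$fiber_id[1:5]) {
    tp <- sec$truth$fibers$fiber_type[i]
    ch <- if (tp == "I") sec$channels$mhc1 else sec$channels$mhc2
    expect_true(all(ch[lab == i] == 200))
  }
  # truth fiber areas equal the label map pixel counts
  expect_equal(sec$truth$fibers$n_pixels,
               tabulate(lab[lab > 0L], nbins = nrow(sec$truth$fibers)))
})

test_that("section generation rejects invalid requests", {
  expect_error(generate_section(make_subject(), optics_params(),
                                n_fibers = 0), ">= 1")
  expect_error(generate_section(tibble::tibble(x = 1), optics_params()),
               "must carry")
  expect_error(optics_params(capillary_spot_od = 0.5), "exceed")
  expect_error(optics_params(calibration_concentrations = c(0.2, 0.4)),
               "blank")
})

test_that("longitudinal sections carry and render the drawn nuclear lengths", {
  # degenerate SD: every nucleus is exactly 11 um long
  sec0 <- generate_longitudinal_section(c(11, 0), n_nuclei = 25, seed = 4)
  expect_true(all(sec0$truth$nuclei$length_um == 11))
  meas0 <- measure_nuclear_lengths(sec0)
  expect_equal(nrow(meas0), 25)
  expect_lt(abs(mean(meas0$length_um) - 11), 0.6)

  # drawn truth is recovered exactly from the truth table,
  # and the image-based measurement tracks it closely
  sec <- generate_longitudinal_section(c(10, 2), n_nuclei = 200, seed = 8)
  drawn <- sec$truth$nuclei$length_um
  expect_equal(mean(drawn), mean(sec$truth$nuclei$length_um))
  meas <- measure_nuclear_lengths(sec)
  expect_equal(nrow(meas), 200)
  expect_lt(abs(mean(meas$length_um) - mean(drawn)) / mean(drawn), 0.05)

  # defaults emulate the 11 +/- 2 um population
  secd <- generate_longitudinal_section(n_nuclei = 150, seed = 9)
  expect_lt(abs(mean(secd$truth$nuclei$length_um) - 11),
            3 * 2 / sqrt(150))
  expect_error(generate_longitudinal_section(c(11, 2), n_nuclei = 0), ">= 1")
})
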
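test_that("fixed seed gives bit-identical cohorts; seeds differ", {
  a <- generate_cohort(cohort_params(seed = 3))
  b <- generate_cohort(cohort_params(seed = 3))
  c <- generate_cohort(cohort_params(seed = 4))
  expect_identical(a, b)
  expect_false(identical(a, c))
  expect_equal(nrow(a), 49)
  expect_equal(as.character(unique(a$group)), c("cyclists", "controls"))
})

test_that("zero-SD parameters collapse every subject onto the group mean", {
  same <- function(cyc, ctl) list(cyclists = c(cyc, 0), controls = c(ctl, 0))
  p <- cohort_params(
    n_per_group = c(cyclists = 5L, controls = 5L),
    mb_type2_mean_sd = same(0.33, 0.35),
    mb_type1_excess_mean_sd = same(25, 84),
    mhc1_pct_mean_sd = same(66, 45.2),
    fcsa_type1_mean_sd = same(6469, 6742),
    fcsa_type2_mean_sd = same(6724, 6891),
    myonuclei_per_fiber_mean_sd = same(4.34, 4.30),
    satellites_per_fiber_mean_sd = same(0.13, 0.15),
    nuclear_length_mean_sd = c(11, 0),
    mrna_rel_mean_sd = same(0.067, 0.088),
    rna_per_mg_mean_sd = same(53.4, 45.1),
    seed = 9
  )
  co <- generate_cohort(p)
  cyc <- co[co$group == "cyclists", ]
  expect_true(all(cyc$mb_type2_mM == 0.33))
  expect_true(all(cyc$mb_type1_mM == 0.33 * 1.25))
  expect_true(all(cyc$pct_type1 == 66))
  expect_true(all(cyc$myonuclei_per_fiber == 4.34))
  expect_true(all(cyc$nuclear_length_um == 11))
  # weighted mean follows exactly from the degenerate components
  expect_equal(unique(cyc$mb_weighted_mM),
               weighted_average_mb(0.33 * 1.25, 0.33, 66))
})

test_that("default cyclist weighted Mb lands near 0.38 mM at n = 29", {
  co <- generate_cohort(cohort_params(seed = 202))
  cyc <- co[co$group == "cyclists", ]
  se <- 0.04 / sqrt(29)
  expect_lt(abs(mean(cyc$mb_weighted_mM) - 0.38), 3 * se)
  # implied per-type defaults: ~0.41 / 0.33 (cyclists)
  expect_lt(abs(mean(cyc$mb_type1_mM) - 0.41), 0.03)
  expect_lt(abs(mean(cyc$mb_type2_mM) - 0.33), 0.02)
})

test_that("sample moments converge to the (truncated) target moments", {
  p <- cohort_params(n_per_group = c(cyclists = 1000L, controls = 1000L),
                     seed = 77)
  co <- generate_cohort(p)
  chk <- function(x, mean, sd, lower = 0) {
    target <- truncnorm_mean(mean, sd, lower)
    expect_lt(abs(mean(x) - target), 3 * sd / sqrt(length(x)))
  }
  cyc <- co[co$group == "cyclists", ]
  ctl <- co[co$group == "controls", ]
  chk(cyc$mb_type2_mM, 0.33, 0.030)
  chk(ctl$mb_type2_mM, 0.35, 0.123)
  chk(cyc$myonuclei_per_fiber, 4.34, 0.76)
  chk(ctl$myonuclei_per_fiber, 4.30, 0.83)
  chk(cyc$mrna_relative, 0.067, 0.019)
  chk(ctl$mrna_relative, 0.088, 0.027)
  chk(cyc$rna_per_mg, 53.4, 29.9)
  chk(ctl$rna_per_mg, 45.1, 26.0)
  chk(cyc$nuclear_length_um, 11, 2, lower = 2)
  # percentages respect their clip bounds and target
  expect_true(all(co$pct_type1 > 0 & co$pct_type1 < 100))
  expect_lt(abs(mean(cyc$pct_type1) - 66.0), 3 * 13.7 / sqrt(1000) + 0.5)
  # all positive quantities strictly positive despite large SDs
  expect_true(all(co$mb_weighted_mM > 0))
  expect_true(all(co$rna_per_mg > 0))
})

test_that("invalid cohort parameters are rejected", {
  expect_error(cohort_params(n_per_group = c(a = 1L, b = 20L)), "n >= 2")
  expect_error(
    cohort_params(mb_type2_mean_sd = list(cyclists = c(0.33, -1),
                                          controls = c(0.35, 0.1))),
    "SD"
  )
  expect_error(cohort_params(n_per_group = c(29, 20)), "named")
})

test_that("qPCR table encodes relative expression exactly (round trip)", {
  co <- generate_cohort(cohort_params(seed = 31))
  ct <- generate_qpcr_table(co, seed = 31)
  expect_true(all(ct$ct_mb > 0 & ct$ct_mb < 45))
  meas <- measure_expression(ct)
  expect_equal(meas$mrna_relative, co$mrna_relative, tolerance = 1e-12)
  expect_equal(meas$rna_per_mg, co$rna_per_mg, tolerance = 1e-12)

  # e = 1 puts the target CT at the housekeeping CT
  co1 <- co[1, ]
  co1$mrna_relative <- 1
  ct1 <- generate_qpcr_table(co1, ct_18s_mean_sd = c(16, 0), seed = 1)
  expect_equal(ct1$ct_mb, ct1$ct_18s)

  # e = 0.067 sits 3.900 cycles above an 18S CT of 16
  co2 <- co[1, ]
  co2$mrna_relative <- 0.067
  ct2 <- generate_qpcr_table(co2, ct_18s_mean_sd = c(16, 0), seed = 1)
  expect_equal(ct2$ct_mb, 16 - log2(0.067), tolerance = 1e-12)
  expect_equal(round(ct2$ct_mb, 3), 19.900)

  co_bad <- co[1, ]
  co_bad$mrna_relative <- 0
  expect_error(generate_qpcr_table(co_bad), "> 0")
})

test_that("cyclist-default qPCR tables recover the 0.067 group mean", {
  co <- generate_cohort(cohort_params(seed = 55))
  meas <- measure_expression(generate_qpcr_table(co, seed = 56))
  cyc <- meas$mrna_relative[meas$group == "cyclists"]
  expect_lt(abs(mean(cyc) - 0.067), 3 * 0.019 / sqrt(29))
})
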
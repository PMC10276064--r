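#' Cohort simulation parameters
#'
#' Bundles the group-level moments that drive the synthetic cohort generator.
#' Defaults describe the two groups the package's analyses are calibrated
#' against: 29 elite cyclists and 20 physically-active controls, using the
#' published group means and SDs for fiber myoglobin concentration, fiber-type
#' distribution, fiber cross-sectional area (FCSA), myonuclear and
#' satellite-cell content, myonuclear length, relative Mb mRNA expression
#' (2^-dCT scale against 18S) and total RNA yield per mg muscle.
#'
#' Per-type myoglobin is parameterised as the type II concentration plus the
#' relative type I excess (in percent), because cohort-level reports print the
#' weighted mean and the type I/II excess rather than per-type moments. The
#' implied type I means are ~0.41 mM (cyclists) and ~0.64 mM (controls), and
#' the implied weighted-mean SDs reproduce the printed 0.04 / 0.19 mM.
#'
#' All quantities are drawn from truncated normal distributions: strictly
#' positive quantities are truncated just above zero and percentages to
#' `[1, 99]`, so that the controls' large Mb SD cannot produce impossible
#' values.
#'
#' @param n_per_group Named integer vector, subjects per group
#'   (`c(cyclists = 29, controls = 20)`). Names define the group labels; the
#'   first group is treated as the intervention/athlete group and the second
#'   as the reference (control) group downstream.
#' @param mb_type2_mean_sd,mb_type1_excess_mean_sd Per-group `c(mean, sd)`
#'   lists: type II fiber Mb concentration (mM) and the percent excess of
#'   type I over type II Mb.
#' @param mhc1_pct_mean_sd Per-group `c(mean, sd)` of the MHC type I fiber
#'   percentage.
#' @param fcsa_type1_mean_sd,fcsa_type2_mean_sd Per-group `c(mean, sd)` FCSA
#'   (um^2) by fiber type.
#' @param myonuclei_per_fiber_mean_sd,satellites_per_fiber_mean_sd Per-group
#'   `c(mean, sd)` counts per fiber cross-section.
#' @param nuclear_length_mean_sd `c(mean, sd)` myonuclear length (um),
#'   common to both groups.
#' @param mrna_rel_mean_sd Per-group `c(mean, sd)` relative Mb mRNA
#'   expression (2^-dCT, dimensionless).
#' @param rna_per_mg_mean_sd Per-group `c(mean, sd)` total RNA yield
#'   (ng per mg muscle).
#' @param mb_mrna_rho Latent (Gaussian-copula) within-group correlation
#'   between the subject's Mb level and relative mRNA expression.
#' @param fiber_mb_cv Within-subject coefficient of variation of per-fiber
#'   Mb concentration around the subject's type mean (biological
#'   fiber-to-fiber variation used when rendering sections).
#' @param seed Integer seed; a fixed seed makes the cohort bit-reproducible.
#'
#' @return An object of class `cohort_params` (a named list).
#' @seealso [generate_cohort()]
#' @export
cohort_params <- function(n_per_group = c(cyclists = 29L, controls = 20L),
                          mb_type2_mean_sd = list(cyclists = c(0.33, 0.030),
                                                  controls = c(0.35, 0.123)),
                          mb_type1_excess_mean_sd = list(cyclists = c(25, 9),
                                                         controls = c(84, 54)),
                          mhc1_pct_mean_sd = list(cyclists = c(66.0, 13.7),
                                                  controls = c(45.2, 10.6)),
                          fcsa_type1_mean_sd = list(cyclists = c(6469, 1600),
                                                    controls = c(6742, 1433)),
                          fcsa_type2_mean_sd = list(cyclists = c(6724, 1813),
                                                    controls = c(6891, 1531)),
                          myonuclei_per_fiber_mean_sd = list(cyclists = c(4.34, 0.76),
                                                             controls = c(4.30, 0.83)),
                          satellites_per_fiber_mean_sd = list(cyclists = c(0.13, 0.05),
                                                              controls = c(0.15, 0.05)),
                          nuclear_length_mean_sd = c(11, 2),
                          mrna_rel_mean_sd = list(cyclists = c(0.067, 0.019),
                                                  controls = c(0.088, 0.027)),
                          rna_per_mg_mean_sd = list(cyclists = c(53.4, 29.9),
                                                    controls = c(45.1, 26.0)),
                          mb_mrna_rho = 0.4,
                          fiber_mb_cv = 0.05,
                          seed = 1L) {
  if (length(n_per_group) != 2 || is.null(names(n_per_group)) ||
      any(!nzchar(names(n_per_group)))) {
    abort("`n_per_group` must be a named length-2 vector of group sizes.")
  }
  if (any(n_per_group < 2)) abort("Each group needs n >= 2 subjects.")
  groups <- names(n_per_group)
  per_group <- list(
    mb_type2_mean_sd = mb_type2_mean_sd,
    mb_type1_excess_mean_sd = mb_type1_excess_mean_sd,
    mhc1_pct_mean_sd = mhc1_pct_mean_sd,
    fcsa_type1_mean_sd = fcsa_type1_mean_sd,
    fcsa_type2_mean_sd = fcsa_type2_mean_sd,
    myonuclei_per_fiber_mean_sd = myonuclei_per_fiber_mean_sd,
    satellites_per_fiber_mean_sd = satellites_per_fiber_mean_sd,
    mrna_rel_mean_sd = mrna_rel_mean_sd,
    rna_per_mg_mean_sd = rna_per_mg_mean_sd
  )
  for (nm in names(per_group)) {
    x <- per_group[[nm]]
    if (!is.list(x) || !all(groups %in% names(x))) {
      abort(paste0("`", nm, "` must be a list with one c(mean, sd) per group."))
    }
    positive <- !(nm %in% "satellites_per_fiber_mean_sd")
    for (g in groups) check_moments(x[[g]], paste0(nm, "$", g), positive)
  }
  check_moments(nuclear_length_mean_sd, "nuclear_length_mean_sd")
  for (g in groups) {
    p <- mhc1_pct_mean_sd[[g]][1]
    if (p <= 0 || p >= 100) abort("Mean MHC-I percentage must lie in (0, 100).")
  }
  if (abs(mb_mrna_rho) > 1) abort("`mb_mrna_rho` must lie in [-1, 1].")
  if (fiber_mb_cv < 0) abort("`fiber_mb_cv` must be >= 0.")
  structure(
    c(list(n_per_group = n_per_group), per_group,
      list(nuclear_length_mean_sd = nuclear_length_mean_sd,
           mb_mrna_rho = mb_mrna_rho,
           fiber_mb_cv = fiber_mb_cv,
           seed = as.integer(seed))),
    class = "cohort_params"
  )
}

#' @export
print.cohort_params <- function(x, ...) {
  cat("<cohort_params>\n")
  cat("  groups: ",
      paste0(names(x$n_per_group), " (n=", x$n_per_group, ")", collapse = ", "),
      "\n", sep = "")
  cat("  seed:   ", x$seed, "\n", sep = "")
  invisible(x)
}

# Truncated-normal quantile transform of a standard-normal latent draw.
.tn_from_z <- function(z, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(rep(mean, length(z)))
  p_lo <- pnorm(lower, mean, sd)
  p_hi <- pnorm(upper, mean, sd)
  qnorm(p_lo + pnorm(z) * (p_hi - p_lo), mean, sd)
}

#' Generate a synthetic subject cohort with known ground truth
#'
#' Draws one row per subject from truncated normal distributions at the
#' group moments held in a [cohort_params()] object. The table is the ground
#' truth that the imaging, densitometry, stereology and expression stages are
#' later verified against: per-type Mb concentration, fiber-type percentage,
#' FCSA, nuclear counts, nuclear length, relative mRNA expression and RNA
#' yield. The subject's weighted Mb concentration is the fiber-type-weighted
#' mean `[Mb]_I * p + [Mb]_II * (1 - p)` with `p` the type I fraction.
#'
#' The subject's mRNA level is coupled to the latent normal behind the type II
#' Mb draw through a Gaussian copula with correlation `mb_mrna_rho`, so pooled
#' Mb/mRNA correlations can be recovered downstream.
#'
#' @param params A [cohort_params()] object.
#' @return A tibble with one row per subject and columns `subject_id`,
#'   `group`, `mb_type1_mM`, `mb_type2_mM`, `mb_weighted_mM`, `pct_type1`,
#'   `fcsa_type1_um2`, `fcsa_type2_um2`, `fcsa_weighted_um2`,
#'   `myonuclei_per_fiber`, `satellites_per_fiber`, `nuclear_length_um`,
#'   `mrna_relative`, `rna_per_mg`.
#' @examples
#' cohort <- generate_cohort(cohort_params(seed = 42))
#' dplyr::count(cohort, group)
#' @export
generate_cohort <- function(params = cohort_params()) {
  if (!inherits(params, "cohort_params")) {
    abort("`params` must be created with cohort_params().")
  }
  eps <- 1e-6
  withr::with_seed(params$seed, {
    rows <- purrr::imap(params$n_per_group, function(n, g) {
      n <- as.integer(n)
      z_mb <- rnorm(n)
      z_ind <- rnorm(n)
      rho <- params$mb_mrna_rho
      z_mrna <- rho * z_mb + sqrt(1 - rho^2) * z_ind

      mb2 <- .tn_from_z(z_mb, params$mb_type2_mean_sd[[g]][1],
                        params$mb_type2_mean_sd[[g]][2], lower = eps)
      # excess bounded at +/-3 SD: keeps the implied type I Mb inside the
      # physiological range the calibration standards span
      ex_m <- params$mb_type1_excess_mean_sd[[g]][1]
      ex_s <- params$mb_type1_excess_mean_sd[[g]][2]
      excess <- rtruncnorm(n, ex_m, ex_s,
                           lower = max(-99, ex_m - 3 * ex_s),
                           upper = ex_m + 3 * ex_s)
      mb1 <- mb2 * (1 + excess / 100)
      pct1 <- rtruncnorm(n, params$mhc1_pct_mean_sd[[g]][1],
                         params$mhc1_pct_mean_sd[[g]][2],
                         lower = 1, upper = 99)
      fcsa1 <- rtruncnorm(n, params$fcsa_type1_mean_sd[[g]][1],
                          params$fcsa_type1_mean_sd[[g]][2], lower = eps)
      fcsa2 <- rtruncnorm(n, params$fcsa_type2_mean_sd[[g]][1],
                          params$fcsa_type2_mean_sd[[g]][2], lower = eps)
      myo <- rtruncnorm(n, params$myonuclei_per_fiber_mean_sd[[g]][1],
                        params$myonuclei_per_fiber_mean_sd[[g]][2],
                        lower = eps)
      sat <- rtruncnorm(n, params$satellites_per_fiber_mean_sd[[g]][1],
                        params$satellites_per_fiber_mean_sd[[g]][2],
                        lower = 0)
      nuc_len <- rtruncnorm(n, params$nuclear_length_mean_sd[1],
                            params$nuclear_length_mean_sd[2], lower = eps)
      mrna <- .tn_from_z(z_mrna, params$mrna_rel_mean_sd[[g]][1],
                         params$mrna_rel_mean_sd[[g]][2], lower = eps)
      rna <- rtruncnorm(n, params$rna_per_mg_mean_sd[[g]][1],
                        params$rna_per_mg_mean_sd[[g]][2], lower = eps)
      p <- pct1 / 100
      tibble(
        group = g,
        mb_type1_mM = mb1,
        mb_type2_mM = mb2,
        mb_weighted_mM = p * mb1 + (1 - p) * mb2,
        pct_type1 = pct1,
        fcsa_type1_um2 = fcsa1,
        fcsa_type2_um2 = fcsa2,
        fcsa_weighted_um2 = p * fcsa1 + (1 - p) * fcsa2,
        myonuclei_per_fiber = myo,
        satellites_per_fiber = sat,
        nuclear_length_um = nuc_len,
        mrna_relative = mrna,
        rna_per_mg = rna
      )
    })
    out <- bind_rows(rows)
    out <- mutate(out,
                  subject_id = sprintf("S%02d", seq_len(nrow(out))),
                  .before = 1)
    out$group <- factor(out$group, levels = names(params$n_per_group))
    out
  })
}

#' Generate a synthetic qPCR cycle-threshold table
#'
#' Builds a per-subject CT table consistent with each subject's ground-truth
#' relative expression `e`: the housekeeping (18S) CT is drawn at the stated
#' moments and the target (Mb) CT is placed at `CT_Mb = CT_18S - log2(e)`, so
#' that `2^-(CT_Mb - CT_18S)` recovers `e` exactly. Muscle-sample mass and
#' total RNA are generated so that `total_rna / muscle_mass` recovers the
#' subject's ground-truth RNA yield.
#'
#' @param cohort Subject tibble from [generate_cohort()]; must carry
#'   `mrna_relative > 0` and `rna_per_mg`.
#' @param ct_18s_mean_sd `c(mean, sd)` of the 18S cycle threshold.
#' @param muscle_mass_mean_sd `c(mean, sd)` of the weighed sample mass (mg).
#' @param seed Integer seed.
#' @return A tibble with `subject_id`, `group`, `ct_mb`, `ct_18s`,
#'   `total_rna_ng`, `muscle_mass_mg`.
#' @export
generate_qpcr_table <- function(cohort,
                                ct_18s_mean_sd = c(16, 1),
                                muscle_mass_mean_sd = c(10, 2),
                                seed = 1L) {
  stopifnot(is.data.frame(cohort))
  if (!all(c("subject_id", "mrna_relative", "rna_per_mg") %in% names(cohort))) {
    abort("`cohort` must carry subject_id, mrna_relative and rna_per_mg.")
  }
  if (any(cohort$mrna_relative <= 0)) {
    abort("Ground-truth relative expression must be > 0.")
  }
  check_moments(ct_18s_mean_sd, "ct_18s_mean_sd")
  check_moments(muscle_mass_mean_sd, "muscle_mass_mean_sd")
  withr::with_seed(seed, {
    n <- nrow(cohort)
    ct18 <- rtruncnorm(n, ct_18s_mean_sd[1], ct_18s_mean_sd[2],
                       lower = 1, upper = 44)
    mass <- rtruncnorm(n, muscle_mass_mean_sd[1], muscle_mass_mean_sd[2],
                       lower = 1)
    tibble(
      subject_id = cohort$subject_id,
      group = cohort$group,
      ct_mb = ct18 - log2(cohort$mrna_relative),
      ct_18s = ct18,
      total_rna_ng = cohort$rna_per_mg * mass,
      muscle_mass_mg = mass
    )
  })
}
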
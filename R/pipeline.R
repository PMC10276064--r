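#' Measure one subject's section end to end
#'
#' Runs the full per-section measurement chain: calibration and densitometry
#' ([measure_section_mb()]), morphometry with the circularity filter and MHC
#' fiber typing ([measure_morphometry()]), fragment detection and
#' stereology ([measure_stereology()]). Per-type Mb concentrations are
#' averaged over up to `n_per_type` randomly sampled included fibers per
#' type (all available when fewer), and combined into the
#' fiber-type-weighted mean with the measured type distribution.
#'
#' @param section A `muscle_section`.
#' @param n_per_type Number of fibers sampled per type for Mb (default 20).
#' @param seed Seed for the fiber sampling.
#' @param stereology_f Correction factor for multiple counting.
#' @param od_margin Capillary-spot exclusion margin (OD).
#' @return List with `subject` (one-row profile tibble), `fibers` (per-fiber
#'   measurements), `fragments`, `curve`, `background`, and `sampled_ids`
#'   (fiber ids used per type for Mb).
#' @export
measure_subject <- function(section, n_per_type = 20, seed = 1L,
                            stereology_f = 2, od_margin = 0.2) {
  stopifnot(inherits(section, "muscle_section"))
  dens <- measure_section_mb(section, od_margin = od_margin)
  morpho <- measure_morphometry(section)
  fragments <- detect_fragments(section)
  stereo <- measure_stereology(section, morpho = morpho,
                               fragments = fragments, f = stereology_f)

  fibers <- left_join(morpho, dens$measurements, by = "fiber_id")
  dist <- fiber_type_distribution(fibers$fiber_type)

  sampled <- withr::with_seed(seed, {
    lapply(c(I = "I", II = "II"), function(tp) {
      ids <- fibers$fiber_id[fibers$included &
                               is.finite(fibers$concentration_mM) &
                               (fibers$fiber_type == tp |
                                  (tp == "II" & fibers$fiber_type == "hybrid"))]
      if (length(ids) > n_per_type) sample(ids, n_per_type) else ids
    })
  })
  mb_of <- function(ids) {
    if (!length(ids)) return(NA_real_)
    mean(fibers$concentration_mM[fibers$fiber_id %in% ids])
  }
  mb1 <- mb_of(sampled$I)
  mb2 <- mb_of(sampled$II)
  mb_w <- if (is.finite(mb1) && is.finite(mb2)) {
    weighted_average_mb(mb1, mb2, dist$pct_type1)
  } else {
    # single-type section: the weighted mean reduces to the present type
    if (is.finite(mb1)) mb1 else mb2
  }
  fcsa_of <- function(tp) {
    v <- fibers$fcsa_um2[fibers$included & fibers$fiber_type == tp]
    if (length(v)) mean(v) else NA_real_
  }
  subject <- tibble(
    subject_id = section$subject_id,
    mb_type1_mM = mb1,
    mb_type2_mM = mb2,
    mb_weighted_mM = mb_w,
    pct_type1 = dist$pct_type1,
    fcsa_type1_um2 = fcsa_of("I"),
    fcsa_type2_um2 = fcsa_of("II"),
    myonuclei_per_fiber = stereo$n_m_f,
    satellites_per_fiber = stereo$satellites_per_fiber,
    n_m_l = stereo$n_m_l,
    mds_pL = stereo$mds_pL,
    satellite_fraction_pct = stereo$satellite_fraction_pct,
    mean_fcsa_um2 = stereo$mean_fcsa_um2,
    n_fibers_counted = stereo$n_fibers_counted,
    calibration_r2 = dens$curve$r_squared
  )
  list(subject = subject, fibers = fibers, fragments = fragments,
       curve = dens$curve, background = dens$background,
       sampled_ids = sampled)
}

# Per-subject section seed derived from the study seed (kept inside int range).
subject_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 7919 * i) %% (2^31 - 1))
}

#' Run the full synthetic study
#'
#' Generates a cohort at the given parameters, renders and measures one
#' section per subject, simulates and evaluates the qPCR table, and runs the
#' two-group comparison battery: assumption-gated tests for weighted Mb,
#' mRNA expression, RNA yield, MDS, fiber-type distribution, FCSA and
#' nuclear counts (Bonferroni m = 1), per-type Mb with Bonferroni m = 2 over
#' the type I/type II pair, and the pooled Spearman correlation of Mb with
#' mRNA expression.
#'
#' @param params [cohort_params()].
#' @param optics [optics_params()].
#' @param n_fibers Fibers rendered per section.
#' @param n_per_type Fibers sampled per type for Mb.
#' @param seed Study seed (defaults to `params$seed`); all section, sampling
#'   and qPCR seeds derive from it.
#' @return An object of class `mb_study`: list with `cohort` (ground truth),
#'   `subjects` (measured per-subject profiles), `comparisons`,
#'   `correlation`, `qpcr`, `params`, `optics`, `seed`.
#' @examples
#' \donttest{
#' study <- run_study(cohort_params(n_per_group = c(cyclists = 3, controls = 3)),
#'                    n_fibers = 15)
#' glance(study)
#' }
#' @export
run_study <- function(params = cohort_params(),
                      optics = optics_params(),
                      n_fibers = 30,
                      n_per_type = 20,
                      seed = NULL) {
  seed <- seed %||% params$seed
  cohort <- generate_cohort(params)

  measured <- purrr::map_dfr(seq_len(nrow(cohort)), function(i) {
    subj <- cohort[i, ]
    sec <- generate_section(subj, optics, n_fibers = n_fibers,
                            seed = subject_seed(seed, i),
                            fiber_mb_cv = params$fiber_mb_cv)
    m <- measure_subject(sec, n_per_type = n_per_type,
                         seed = subject_seed(seed, i) + 1L)
    mutate(m$subject, subject_id = subj$subject_id, group = subj$group,
           .before = 1)
  })
  qpcr <- generate_qpcr_table(cohort, seed = subject_seed(seed, 0L)) |>
    measure_expression()
  measured <- left_join(measured,
                        select(qpcr, "subject_id", "mrna_relative",
                               "rna_per_mg"),
                        by = "subject_id")

  vars_m1 <- c("mb_weighted_mM", "mrna_relative", "rna_per_mg", "mds_pL",
               "pct_type1", "fcsa_type1_um2", "fcsa_type2_um2",
               "myonuclei_per_fiber", "satellites_per_fiber",
               "satellite_fraction_pct")
  try_compare <- function(variable, adjust_m = 1) {
    tryCatch(
      compare_groups(measured, variable, adjust_m = adjust_m),
      error = function(e) {
        warn(sprintf("Comparison of %s skipped: %s", variable,
                     conditionMessage(e)))
        NULL
      })
  }
  comparisons <- bind_rows(
    purrr::map_dfr(vars_m1, try_compare),
    purrr::map_dfr(c("mb_type1_mM", "mb_type2_mM"), try_compare,
                   adjust_m = 2)
  )
  correlation <- pooled_spearman(measured$mb_weighted_mM,
                                 measured$mrna_relative)

  structure(list(cohort = cohort, subjects = measured,
                 comparisons = comparisons, correlation = correlation,
                 qpcr = qpcr, params = params, optics = optics,
                 seed = as.integer(seed)),
            class = "mb_study")
}

#' @export
print.mb_study <- function(x, ...) {
  cat("<mb_study> ", nrow(x$subjects), " subjects (",
      paste0(levels(x$subjects$group), collapse = " vs "), "), seed ",
      x$seed, "\n", sep = "")
  sig <- x$comparisons$variable[x$comparisons$p_adjusted < 0.05]
  cat("  significant (adj. P < 0.05): ",
      if (length(sig)) paste(sig, collapse = ", ") else "none", "\n",
      sep = "")
  cat(sprintf("  pooled Spearman rho = %.2f (P = %.3f, %.0f%% of variance)\n",
              x$correlation$rho, x$correlation$p_value,
              x$correlation$explained_variance_pct))
  invisible(x)
}
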
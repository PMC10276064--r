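#' Tidy a calibration curve
#'
#' @param x A `calibration_curve`.
#' @param ... Unused.
#' @return Tibble with one row per model term (intercept, slope), with
#'   estimate, standard error, statistic and p-value.
#' @export
tidy.calibration_curve <- function(x, ...) {
  s <- suppressWarnings(summary(x$fit))$coefficients
  tibble(
    term = c("intercept", "slope"),
    estimate = s[, 1],
    std.error = s[, 2],
    statistic = s[, 3],
    p.value = s[, 4]
  )
}

#' One-row summary of a calibration curve
#'
#' @param x A `calibration_curve`.
#' @param ... Unused.
#' @return Tibble with `slope`, `intercept`, `r.squared`, `n_standards`,
#'   `max_concentration`.
#' @export
glance.calibration_curve <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept, r.squared = x$r_squared,
         n_standards = x$n_standards, max_concentration = x$max_concentration)
}

#' Tidy a study: the comparison table
#'
#' @param x An `mb_study` from [run_study()].
#' @param ... Unused.
#' @return The group-comparison tibble (one row per variable).
#' @export
tidy.mb_study <- function(x, ...) as_tibble(x$comparisons)

#' One-row study summary
#'
#' @param x An `mb_study`.
#' @param ... Unused.
#' @return Tibble with the headline quantities: per-group weighted Mb and
#'   mRNA means, their percent differences, MDS per group, and the pooled
#'   Spearman correlation.
#' @export
glance.mb_study <- function(x, ...) {
  g <- levels(x$subjects$group)
  msd <- function(v, grp) mean(x$subjects[[v]][x$subjects$group == grp],
                               na.rm = TRUE)
  cmp <- function(v) x$comparisons$percent_difference[
    x$comparisons$variable == v]
  tibble(
    mb_weighted_1 = msd("mb_weighted_mM", g[1]),
    mb_weighted_ref = msd("mb_weighted_mM", g[2]),
    mb_pct_lower = cmp("mb_weighted_mM"),
    mrna_1 = msd("mrna_relative", g[1]),
    mrna_ref = msd("mrna_relative", g[2]),
    mrna_pct_lower = cmp("mrna_relative"),
    mds_1 = msd("mds_pL", g[1]),
    mds_ref = msd("mds_pL", g[2]),
    spearman_rho = x$correlation$rho,
    explained_variance_pct = x$correlation$explained_variance_pct,
    n = nrow(x$subjects)
  )
}
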
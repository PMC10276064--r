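#' Convert transmission gray values to optical density
#'
#' Beer-Lambert transmission densitometry: `OD = -log10(I / I0)` where `I` is
#' the measured gray value and `I0` the incident (background) intensity.
#' Intensities above the background (possible under noise) clamp to OD 0.
#'
#' @param intensity Measured gray value(s), > 0.
#' @param background Background gray value `I0`, > 0.
#' @return Optical density (OD), same length as `intensity`.
#' @examples
#' gray_to_absorbance(20, 200)   # one decade of attenuation -> OD 1
#' @export
gray_to_absorbance <- function(intensity, background) {
  if (any(!is.finite(intensity)) || any(intensity <= 0)) {
    abort("`intensity` must be positive and finite.")
  }
  if (length(background) != 1 || !is.finite(background) || background <= 0) {
    abort("`background` must be a single positive value.")
  }
  pmax(-log10(intensity / background), 0)
}

# Inverse mapping, used for round-trip checks.
absorbance_to_gray <- function(od, background) background * 10^(-od)

#' Estimate the background (incident) intensity of a section
#'
#' The modal gray value of the fiber-free margin, excluding the calibration
#' blocks. The mode is robust against dark outliers (spots, block edges).
#'
#' @param section A `muscle_section`.
#' @return Scalar gray value.
#' @export
estimate_background <- function(section) {
  stopifnot(inherits(section, "muscle_section"))
  tr <- section$channels$transmission
  if (!length(section$margin_cols)) abort("Section has no reserved margin.")
  in_margin <- matrix(FALSE, nrow(tr), ncol(tr))
  in_margin[, section$margin_cols] <- TRUE
  cal <- section$truth$calibration
  if (!is.null(cal)) {
    for (b in seq_len(nrow(cal))) {
      in_margin[cal$row0[b]:cal$row1[b], cal$col0[b]:cal$col1[b]] <- FALSE
    }
  }
  int_mode(tr[in_margin])
}

#' Read the calibration standards off a section
#'
#' Extracts the mean gray value of each calibration block region and converts
#' it to absorbance against the supplied (or estimated) background.
#'
#' @param section A `muscle_section`.
#' @param regions Tibble of block regions with `concentration_mM`, `row0`,
#'   `row1`, `col0`, `col1`; defaults to the section's truth regions (block
#'   positions are part of the assay design, not a measurement).
#' @param background Background gray value; estimated from the margin when
#'   `NULL`.
#' @return Tibble of calibration standards: `concentration_mM`, `mean_gray`,
#'   `absorbance`.
#' @export
read_calibration_standards <- function(section, regions = NULL,
                                       background = NULL) {
  stopifnot(inherits(section, "muscle_section"))
  regions <- regions %||% section$truth$calibration
  if (is.null(regions) || nrow(regions) < 2) {
    abort("Need at least two calibration block regions.")
  }
  background <- background %||% estimate_background(section)
  tr <- section$channels$transmission
  mg <- vapply(seq_len(nrow(regions)), function(b) {
    mean(tr[regions$row0[b]:regions$row1[b], regions$col0[b]:regions$col1[b]])
  }, numeric(1))
  tibble(
    concentration_mM = regions$concentration_mM,
    mean_gray = mg,
    absorbance = gray_to_absorbance(pmax(mg, 0.5), background)
  )
}

#' Fit the absorbance-vs-concentration calibration line
#'
#' Ordinary least squares of `absorbance ~ concentration` over the
#' calibration standards. The intercept is estimated (not forced through the
#' origin) to absorb section-thickness or fixation offsets; on clean data it
#' is ~0 and the slope equals the effective extinction scale (OD/mM).
#' A non-positive slope is an assay failure and raises an error.
#'
#' @param standards Tibble from [read_calibration_standards()] (or any table
#'   with `concentration_mM` and `absorbance`).
#' @return A `calibration_curve` object with fields `slope`, `intercept`,
#'   `r_squared`, `n_standards`, `max_concentration`.
#' @examples
#' std <- tibble::tibble(concentration_mM = c(0, 0.2, 0.4, 0.6, 0.8),
#'                       absorbance = 0.9 * c(0, 0.2, 0.4, 0.6, 0.8) + 0.05)
#' fit_calibration(std)
#' @export
fit_calibration <- function(standards) {
  stopifnot(is.data.frame(standards))
  if (!all(c("concentration_mM", "absorbance") %in% names(standards))) {
    abort("`standards` needs columns concentration_mM and absorbance.")
  }
  if (nrow(standards) < 2 ||
      length(unique(standards$concentration_mM)) < 2) {
    abort("Need >= 2 standards with distinct concentrations.")
  }
  fit <- lm(absorbance ~ concentration_mM, data = standards)
  slope <- unname(coef(fit)[2])
  if (!is.finite(slope) || slope <= 0) {
    abort("Calibration slope is not positive: assay failure.")
  }
  ss_tot <- sum((standards$absorbance - mean(standards$absorbance))^2)
  r2 <- if (ss_tot > 0) 1 - sum(fit$residuals^2) / ss_tot else NA_real_
  structure(list(
    slope = slope,
    intercept = unname(coef(fit)[1]),
    r_squared = r2,
    n_standards = nrow(standards),
    max_concentration = max(standards$concentration_mM),
    fit = fit
  ), class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "<calibration_curve> OD = %.4f * [Mb] + %.4f  (r^2 = %.4f, n = %d)\n",
    x$slope, x$intercept, x$r_squared, x$n_standards))
  invisible(x)
}

#' Flag capillary peroxidase spots for exclusion
#'
#' Hemoglobin in capillaries produces near-black peroxidase spots that must
#' not enter the fiber's myoglobin estimate. A pixel is excluded when its OD
#' exceeds the OD of the highest calibration standard plus a margin.
#'
#' @param od Vector of per-pixel optical densities for one fiber.
#' @param curve A `calibration_curve`.
#' @param od_margin OD margin above the highest standard (default 0.2).
#' @return List with `include` (logical mask), `n_excluded`, and
#'   `threshold_od`. Errors if every pixel would be excluded.
#' @export
exclude_capillary_spots <- function(od, curve, od_margin = 0.2) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (!length(od)) abort("Empty pixel set.")
  thr <- curve$intercept + curve$slope * curve$max_concentration + od_margin
  include <- od <= thr
  if (!any(include)) {
    abort("All pixels excluded as capillary spots: fiber unusable.")
  }
  list(include = include, n_excluded = sum(!include), threshold_od = thr)
}

#' Myoglobin concentration of one fiber
#'
#' Mean included OD of the fiber's pixels, inverted through the calibration
#' line: `[Mb] = (mean OD - intercept) / slope`, clamped at 0 (noise can push
#' low-Mb fibers below the intercept; a clamp is logged as a warning).
#'
#' @param od Per-pixel ODs of the fiber.
#' @param curve A `calibration_curve`.
#' @param fiber_id Identifier carried into the result.
#' @param od_margin Spot-exclusion margin, see [exclude_capillary_spots()].
#' @return One-row tibble: `fiber_id`, `mean_od`, `concentration_mM`,
#'   `n_pixels_used`, `n_pixels_excluded`.
#' @export
fiber_mb_concentration <- function(od, curve, fiber_id = NA_integer_,
                                   od_margin = 0.2) {
  ex <- exclude_capillary_spots(od, curve, od_margin)
  m_od <- mean(od[ex$include])
  conc <- (m_od - curve$intercept) / curve$slope
  if (conc < 0) {
    warn(sprintf("Fiber %s: fitted concentration %.4f mM clamped to 0.",
                 as.character(fiber_id), conc))
    conc <- 0
  }
  tibble(fiber_id = fiber_id, mean_od = m_od, concentration_mM = conc,
         n_pixels_used = sum(ex$include), n_pixels_excluded = ex$n_excluded)
}

#' Fiber-type-weighted average myoglobin concentration
#'
#' `[Mb]_avg = [Mb]_I * p + [Mb]_II * (1 - p)` with `p` the type I fiber
#' fraction, the subject-level summary used for group comparisons.
#'
#' @param mb_type1,mb_type2 Mean Mb concentration (mM) in type I / II fibers.
#' @param pct_type1 Percentage of type I fibers, in `[0, 100]`.
#' @return Weighted concentration (mM); vectorized.
#' @examples
#' weighted_average_mb(0.41, 0.33, 66)  # 0.3828
#' @export
weighted_average_mb <- function(mb_type1, mb_type2, pct_type1) {
  if (any(pct_type1 < 0 | pct_type1 > 100)) {
    abort("`pct_type1` must lie in [0, 100].")
  }
  p <- pct_type1 / 100
  mb_type1 * p + mb_type2 * (1 - p)
}

#' Per-fiber densitometry of a whole section
#'
#' Runs the full measurement chain on a section: background estimation,
#' calibration fit, per-fiber OD extraction with capillary-spot exclusion,
#' and inversion to concentration.
#'
#' @param section A `muscle_section`.
#' @param curve Optional pre-fitted `calibration_curve`; fitted from the
#'   section's own calibration blocks when `NULL`.
#' @param fiber_ids Fibers to measure (default: all in the label map).
#' @param od_margin Spot-exclusion margin.
#' @return List with `curve`, `background`, and `measurements` (one row per
#'   fiber, see [fiber_mb_concentration()]).
#' @export
measure_section_mb <- function(section, curve = NULL, fiber_ids = NULL,
                               od_margin = 0.2) {
  stopifnot(inherits(section, "muscle_section"))
  bg <- estimate_background(section)
  if (is.null(curve)) {
    curve <- fit_calibration(read_calibration_standards(section,
                                                        background = bg))
  }
  lab <- section$truth$label
  tr <- section$channels$transmission
  fiber_ids <- fiber_ids %||% sort(unique(lab[lab > 0L]))
  meas <- purrr::map_dfr(fiber_ids, function(i) {
    px <- tr[lab == i]
    od <- gray_to_absorbance(pmax(px, 0.5), bg)
    tryCatch(
      fiber_mb_concentration(od, curve, fiber_id = i, od_margin = od_margin),
      error = function(e) {
        warn(sprintf("Fiber %d unusable (%s); recorded as NA.",
                     i, conditionMessage(e)))
        tibble(fiber_id = i, mean_od = NA_real_,
               concentration_mM = NA_real_,
               n_pixels_used = 0L, n_pixels_excluded = length(od))
      })
  })
  list(curve = curve, background = bg, measurements = meas)
}
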
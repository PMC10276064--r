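#' Classify DAPI-positive nuclear fragments
#'
#' Positional/Pax7 classification of nuclear fragments in a transverse
#' section: a fragment against the basal lamina is a myonucleus unless it is
#' Pax7-positive, in which case it is a satellite cell; a fragment inside the
#' fiber but not in contact with the lamina is a central nucleus; a fragment
#' between basal laminas (not inside any fiber) is interstitial (fibroblast,
#' endothelial cell or macrophage). Only myonuclei count toward the
#' per-cross-section myonuclear number.
#'
#' @param fragments Tibble with logical columns `touches_basal_lamina`,
#'   `inside_fiber`, `pax7_positive`.
#' @return `fragments` with an `assigned_class` column
#'   (`myonucleus` / `satellite` / `central` / `interstitial`).
#' @export
classify_fragments <- function(fragments) {
  stopifnot(is.data.frame(fragments))
  need <- c("touches_basal_lamina", "inside_fiber", "pax7_positive")
  if (!all(need %in% names(fragments))) {
    abort(paste("`fragments` must carry:", paste(need, collapse = ", ")))
  }
  if (anyNA(fragments[need])) abort("Fragment flags must not be NA.")
  mutate(fragments, assigned_class = dplyr::case_when(
    !.data$inside_fiber ~ "interstitial",
    .data$touches_basal_lamina & .data$pax7_positive ~ "satellite",
    .data$touches_basal_lamina ~ "myonucleus",
    TRUE ~ "central"
  ))
}

#' Multiple-counting correction factor
#'
#' The number of consecutive sections of thickness `d_s` in which an average
#' nucleus of length `l_nuc` produces a detectable fragment, given the
#' smallest detectable fragment `d_min`:
#' `F = floor((l_nuc - d_min) / d_s) + 1`. With 11 um nuclei, 10 um sections
#' and a 1 um detection limit every nucleus appears in two consecutive
#' sections, so F = 2 and each nucleus is counted twice.
#'
#' @param l_nuc Average myonuclear length, um; must exceed `d_min`.
#' @param d_s Section thickness, um.
#' @param d_min Smallest detectable fragment, um.
#' @return Integer correction factor, >= 1.
#' @examples
#' correction_factor(11, 10, 1)  # 2
#' @export
correction_factor <- function(l_nuc, d_s = 10, d_min = 1) {
  if (any(l_nuc <= 0) || any(d_s <= 0) || any(d_min <= 0)) {
    abort("All stereology lengths must be > 0.")
  }
  if (any(l_nuc <= d_min)) {
    abort("`l_nuc` must exceed the detection limit `d_min`.")
  }
  as.integer(floor((l_nuc - d_min) / d_s) + 1)
}

#' Myonuclei per mm of fiber length
#'
#' `N_m,l = N_m,f * L_f / (D_s * F)`: the fragment count per cross-section
#' scaled to a fiber segment of length `l_f`, corrected for each nucleus
#' being counted in `f` consecutive sections of thickness `d_s`.
#'
#' @param n_m_f Myonuclear fragments per fiber cross-section.
#' @param l_f Fiber segment length, um (1000 = one mm).
#' @param d_s Section thickness, um.
#' @param f Correction factor from [correction_factor()].
#' @return Myonuclei per `l_f` of fiber (per mm with the default).
#' @examples
#' nuclei_per_mm(4.34, 1000, 10, 2)  # 217
#' @export
nuclei_per_mm <- function(n_m_f, l_f = 1000, d_s = 10, f = 2) {
  if (any(d_s * f == 0)) abort("Zero divisor in nuclei_per_mm().")
  if (any(c(l_f, d_s, f) <= 0)) abort("All arguments must be > 0.")
  n_m_f * l_f / (d_s * f)
}

#' Myonuclear domain size
#'
#' `MDS = FCSA / N_m,l`, the cytoplasmic volume served by one myonucleus.
#' With FCSA in um^2 and `n_m_l` per mm, the ratio is numerically in pL
#' (um^2 * mm / 1000 = 10^3 um^3 = 1 pL).
#'
#' @param fcsa Fiber cross-sectional area, um^2.
#' @param n_m_l Myonuclei per mm fiber, > 0.
#' @return Domain size in pL.
#' @examples
#' mds(6556, 217)  # ~30.2 pL
#' @export
mds <- function(fcsa, n_m_l) {
  if (any(n_m_l <= 0)) abort("`n_m_l` must be > 0.")
  fcsa / n_m_l
}

#' Satellite cells as a percentage of total nuclei
#'
#' `satellites / (myonuclei + satellites) * 100`, both per fiber
#' cross-section.
#'
#' @param satellites_per_fiber,myonuclei_per_fiber Mean counts per fiber.
#' @return Percentage.
#' @examples
#' satellite_fraction(0.13, 4.34)  # ~2.91
#' @export
satellite_fraction <- function(satellites_per_fiber, myonuclei_per_fiber) {
  if (any(satellites_per_fiber < 0) || any(myonuclei_per_fiber < 0)) {
    abort("Counts must be >= 0.")
  }
  tot <- satellites_per_fiber + myonuclei_per_fiber
  if (any(tot == 0)) abort("Zero total nuclei.")
  100 * satellites_per_fiber / tot
}

#' Detect nuclear fragments in a section's fluorescence channels
#'
#' Segments DAPI-positive blobs (connected components above threshold via
#' [EBImage::bwlabel()]), then derives each fragment's positional flags:
#' `inside_fiber` from the fiber label under the fragment centroid,
#' `touches_basal_lamina` when any WGA-positive pixel lies within one pixel
#' of the fragment, and `pax7_positive` from the mean Pax7 signal over the
#' fragment. Flags are classified with [classify_fragments()].
#'
#' @param section A `muscle_section`.
#' @param intensity_threshold Gray level above which a pixel is positive.
#' @return Tibble with one row per detected fragment: centroid (`row`,
#'   `col`), `fiber_id` (NA outside fibers), the three flags and
#'   `assigned_class`.
#' @export
detect_fragments <- function(section, intensity_threshold = 128) {
  stopifnot(inherits(section, "muscle_section"))
  dapi <- section$channels$dapi
  wga <- section$channels$wga
  pax7 <- section$channels$pax7
  lab <- section$truth$label
  comp <- EBImage::bwlabel(dapi > intensity_threshold)
  comp <- matrix(as.integer(comp), nrow(dapi), ncol(dapi))
  n <- max(comp)
  if (n == 0) {
    return(classify_fragments(tibble(
      fragment_id = integer(), row = numeric(), col = numeric(),
      fiber_id = integer(), touches_basal_lamina = logical(),
      inside_fiber = logical(), pax7_positive = logical())))
  }
  wga_pos <- wga > intensity_threshold
  # one-pixel dilation of the lamina for the contact test
  wga_near <- wga_pos
  for (dr in -1:1) for (dc in -1:1) {
    wga_near <- wga_near | shift_mat(wga_pos, dr, dc, FALSE)
  }
  H <- nrow(dapi)
  idx <- which(comp > 0L)
  by_comp <- split(idx, comp[idx])
  out <- purrr::map_dfr(seq_len(n), function(k) {
    px <- by_comp[[as.character(k)]]
    r <- (px - 1L) %% H + 1L
    c <- (px - 1L) %/% H + 1L
    fib <- lab[round(mean(r)), round(mean(c))]
    tibble(
      fragment_id = k, row = mean(r), col = mean(c),
      fiber_id = if (fib > 0L) as.integer(fib) else NA_integer_,
      touches_basal_lamina = any(wga_near[px]),
      inside_fiber = fib > 0L,
      pax7_positive = mean(pax7[px]) > intensity_threshold / 2
    )
  })
  classify_fragments(out)
}

#' Measure average myonuclear length on a longitudinal section
#'
#' Labels DAPI blobs and estimates each nucleus' major-axis length from the
#' second moments of its pixel coordinates (for a filled ellipse the
#' major-axis length is `4 * sqrt(largest eigenvalue)` of the coordinate
#' covariance), scaled to um.
#'
#' @param section A longitudinal `muscle_section` from
#'   [generate_longitudinal_section()].
#' @param intensity_threshold Positivity threshold.
#' @return Tibble with `nucleus_id` and `length_um` per detected nucleus.
#' @export
measure_nuclear_lengths <- function(section, intensity_threshold = 128) {
  stopifnot(inherits(section, "muscle_section"))
  dapi <- section$channels$dapi
  comp <- EBImage::bwlabel(dapi > intensity_threshold)
  comp <- matrix(as.integer(comp), nrow(dapi), ncol(dapi))
  n <- max(comp)
  if (n == 0) abort("No nuclei detected.")
  H <- nrow(dapi)
  idx <- which(comp > 0L)
  by_comp <- split(idx, comp[idx])
  purrr::map_dfr(seq_len(n), function(k) {
    px <- by_comp[[as.character(k)]]
    y <- (px - 1L) %% H + 1L
    x <- (px - 1L) %/% H + 1L
    cv <- stats::cov(cbind(as.numeric(x), as.numeric(y)))
    lam <- max(eigen(cv, symmetric = TRUE, only.values = TRUE)$values)
    tibble(nucleus_id = k, length_um = 4 * sqrt(lam) * section$pixel_size)
  })
}

#' Per-section myonuclear stereology
#'
#' Counts detected myonuclear and satellite fragments per fiber over fibers
#' passing the circularity filter (counting in circular cells only avoids
#' overestimating the myonuclear domain), then computes nuclei per mm, the
#' myonuclear domain size from the same fibers' mean FCSA, and the satellite
#' fraction.
#'
#' @param section A `muscle_section`.
#' @param morpho Optional result of [measure_morphometry()] for the section.
#' @param fragments Optional result of [detect_fragments()].
#' @param l_f Fiber segment length, um.
#' @param d_s Section thickness, um.
#' @param f Correction factor (default the package's global 2, derived from
#'   11 um nuclei in 10 um sections with a 1 um detection limit).
#' @return One-row tibble: `n_m_f`, `satellites_per_fiber`, `n_m_l`,
#'   `mean_fcsa_um2`, `mds_pL`, `satellite_fraction_pct`, `n_fibers_counted`.
#' @export
measure_stereology <- function(section, morpho = NULL, fragments = NULL,
                               l_f = 1000, d_s = 10, f = 2) {
  stopifnot(inherits(section, "muscle_section"))
  morpho <- morpho %||% measure_morphometry(section)
  fragments <- fragments %||% detect_fragments(section)
  counted <- morpho$fiber_id[morpho$included]
  if (!length(counted)) abort("No fibers pass the circularity filter.")
  fr <- filter(fragments, .data$fiber_id %in% counted)
  n_myo <- vapply(counted, function(i) {
    sum(fr$fiber_id == i & fr$assigned_class == "myonucleus", na.rm = TRUE)
  }, numeric(1))
  n_sat <- vapply(counted, function(i) {
    sum(fr$fiber_id == i & fr$assigned_class == "satellite", na.rm = TRUE)
  }, numeric(1))
  n_m_f <- mean(n_myo)
  sat_f <- mean(n_sat)
  n_m_l <- nuclei_per_mm(n_m_f, l_f = l_f, d_s = d_s, f = f)
  mean_fcsa <- mean(morpho$fcsa_um2[morpho$included])
  tibble(
    n_m_f = n_m_f,
    satellites_per_fiber = sat_f,
    n_m_l = n_m_l,
    mean_fcsa_um2 = mean_fcsa,
    mds_pL = if (n_m_l > 0) mds(mean_fcsa, n_m_l) else NA_real_,
    satellite_fraction_pct = if (n_m_f + sat_f > 0)
      satellite_fraction(sat_f, n_m_f) else NA_real_,
    n_fibers_counted = length(counted)
  )
}
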
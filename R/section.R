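#' Imaging-model parameters for synthetic sections
#'
#' Describes the simplified imaging physics used to render synthetic
#' transmission (peroxidase densitometry) and fluorescence channels: an
#' incident intensity `I0`, a Beer-Lambert mapping of myoglobin concentration
#' to optical density through `extinction_scale`, additive Gaussian read
#' noise, and quantization to `bit_depth` bits. Calibration blocks of known
#' concentration are rendered in a reserved image margin; capillary
#' peroxidase "black spots" are stamped onto fiber boundaries at a fixed,
#' near-opaque optical density.
#'
#' @param bit_depth Bits per pixel of the quantized transmission image.
#' @param background_intensity Incident/background gray value `I0`.
#' @param extinction_scale Optical density per mM of myoglobin (path length
#'   and molar absorptivity folded into one scale).
#' @param noise_sd Additive Gaussian noise SD in gray levels (0 disables
#'   noise; quantization still applies).
#' @param pixel_size Pixel edge length in um/px.
#' @param pixel_aspect Height/width ratio of a pixel (1 = square pixels);
#'   the y pixel size is `pixel_size * pixel_aspect`.
#' @param calibration_concentrations Myoglobin concentrations (mM) of the
#'   rendered calibration standards; must include 0 and span the simulated
#'   range.
#' @param capillary_spot_density Expected capillary spots per fiber.
#' @param capillary_spot_od Optical density of a capillary spot; must exceed
#'   the OD of the highest calibration standard.
#' @return An object of class `optics_params`.
#' @export
optics_params <- function(bit_depth = 8L,
                          background_intensity = 200,
                          extinction_scale = 1.0,
                          noise_sd = 2,
                          pixel_size = 2,
                          pixel_aspect = 1,
                          calibration_concentrations = c(0, 0.2, 0.4, 0.8, 1.2, 1.6),
                          capillary_spot_density = 1,
                          capillary_spot_od = 2.0) {
  if (extinction_scale <= 0) abort("`extinction_scale` must be > 0.")
  if (!0 %in% calibration_concentrations) {
    abort("`calibration_concentrations` must include a blank (0 mM) standard.")
  }
  if (length(calibration_concentrations) < 2) {
    abort("Need at least two calibration standards.")
  }
  if (capillary_spot_od <= extinction_scale * max(calibration_concentrations)) {
    abort("`capillary_spot_od` must exceed the OD of the highest standard.")
  }
  if (pixel_size <= 0 || pixel_aspect <= 0) {
    abort("`pixel_size` and `pixel_aspect` must be > 0.")
  }
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (background_intensity <= 0 ||
      background_intensity > 2^bit_depth - 1) {
    abort("`background_intensity` must lie in (0, 2^bit_depth - 1].")
  }
  structure(list(
    bit_depth = as.integer(bit_depth),
    background_intensity = background_intensity,
    extinction_scale = extinction_scale,
    noise_sd = noise_sd,
    pixel_size = pixel_size,
    pixel_aspect = pixel_aspect,
    calibration_concentrations = sort(calibration_concentrations),
    capillary_spot_density = capillary_spot_density,
    capillary_spot_od = capillary_spot_od
  ), class = "optics_params")
}

#' @export
print.optics_params <- function(x, ...) {
  cat("<optics_params> I0=", x$background_intensity,
      ", extinction=", x$extinction_scale, " OD/mM, noise_sd=", x$noise_sd,
      ", pixel=", x$pixel_size, " um, standards={",
      paste(x$calibration_concentrations, collapse = ", "), "} mM\n", sep = "")
  invisible(x)
}

# ---- low-level raster helpers ------------------------------------------------

# Shift matrix by (dr, dc), filling exposed cells with `fill`.
shift_mat <- function(m, dr, dc, fill) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(fill, H, W)
  rs <- max(1, 1 + dr):min(H, H + dr)
  cs <- max(1, 1 + dc):min(W, W + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# 8-neighbourhood binary erosion.
erode8 <- function(mask) {
  out <- mask
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    out <- out & shift_mat(mask, dr, dc, FALSE)
  }
  out
}

# 4-neighbour boundary of an integer label map (outside counted as different).
label_boundary <- function(lab) {
  b <- matrix(FALSE, nrow(lab), ncol(lab))
  for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    b <- b | (lab != shift_mat(lab, d[1], d[2], -1L))
  }
  b
}

# 8-neighbourhood binary dilation.
dilate8 <- function(mask) {
  out <- mask
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    out <- out | shift_mat(mask, dr, dc, FALSE)
  }
  out
}

# Sample up to k candidate centers keeping min_sep (px) from already placed.
place_centers <- function(cand, k, placed, min_sep) {
  sel <- matrix(numeric(0), 0, 2)
  if (k <= 0 || nrow(cand) == 0) return(sel)
  ord <- sample.int(nrow(cand))
  for (j in ord) {
    p <- cand[j, , drop = FALSE]
    pts <- rbind(placed, sel)
    ok <- nrow(pts) == 0 ||
      min((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2) >= min_sep^2
    if (ok) {
      sel <- rbind(sel, p)
      if (nrow(sel) == k) break
    }
  }
  sel
}

# Power-diagram-style tessellation with Lloyd relaxation on the pixel grid.
# Returns an integer label matrix (H x W) with labels 1..n.
voronoi_labels <- function(H, W, n, weights, n_iter = 8) {
  sr <- runif(n, 1, H)
  sc <- runif(n, 1, W)
  rows <- matrix(rep(seq_len(H), W), H)
  cols <- matrix(rep(seq_len(W), each = H), H)
  lab <- matrix(1L, H, W)
  for (it in seq_len(n_iter)) {
    best <- matrix(Inf, H, W)
    for (i in seq_len(n)) {
      d <- ((rows - sr[i])^2 + (cols - sc[i])^2) / weights[i]
      upd <- d < best
      best[upd] <- d[upd]
      lab[upd] <- i
    }
    for (i in seq_len(n)) {
      px <- lab == i
      if (any(px)) {
        sr[i] <- mean(rows[px])
        sc[i] <- mean(cols[px])
      } else {
        sr[i] <- runif(1, 1, H)
        sc[i] <- runif(1, 1, W)
      }
    }
  }
  lab
}

# ---- section generator -------------------------------------------------------

#' Render a synthetic muscle cross-section with ground truth
#'
#' Builds a multichannel image of a transverse muscle section for one
#' subject. Fibers are laid out as a bounded Voronoi tessellation (Lloyd
#' relaxed, area-weighted by the subject's per-type FCSA) and separated by a
#' thin WGA-positive basal-lamina network. Each fiber receives a type from
#' the subject's fiber-type distribution and a myoglobin concentration drawn
#' around the subject's per-type mean; transmission intensity follows
#' Beer-Lambert (`I0 * 10^-OD`) with additive noise and quantization.
#' Calibration blocks of known concentration are rendered in a reserved
#' left margin; capillary peroxidase spots are stamped at fiber boundaries;
#' DAPI-positive nuclear fragments are positioned by class (myonuclei and
#' Pax7-positive satellite cells against the lamina, rare central nuclei in
#' the fiber interior, interstitial nuclei between laminas). Everything
#' rendered is recorded in a ground-truth side table.
#'
#' @param subject One-row data frame (a row of [generate_cohort()]) carrying
#'   `mb_type1_mM`, `mb_type2_mM`, `pct_type1`, `fcsa_type1_um2`,
#'   `fcsa_type2_um2`, `myonuclei_per_fiber`, `satellites_per_fiber`.
#' @param optics An [optics_params()] object.
#' @param n_fibers Number of fibers to render.
#' @param seed Integer seed.
#' @param fiber_mb_cv Fiber-to-fiber CV of Mb concentration around the
#'   subject's type mean.
#' @param central_rate,interstitial_rate Expected central / interstitial
#'   fragments per fiber, as a fraction of the myonuclear rate.
#' @param fragment_radius_px Rendered nuclear fragment radius (px).
#' @return An object of class `muscle_section`: a list with `channels`
#'   (`transmission`, `mhc1`, `mhc2`, `dapi`, `pax7`, `wga` matrices),
#'   `pixel_size`, `pixel_aspect`, `optics`, and `truth` (label map plus
#'   `fibers`, `fragments`, `spots`, `calibration` tibbles).
#' @examples
#' subj <- generate_cohort(cohort_params(seed = 7))[1, ]
#' sec <- generate_section(subj, optics_params(noise_sd = 0), n_fibers = 12,
#'                         seed = 7)
#' sec
#' @export
generate_section <- function(subject,
                             optics = optics_params(),
                             n_fibers = 30,
                             seed = 1L,
                             fiber_mb_cv = 0.05,
                             central_rate = 0.01,
                             interstitial_rate = 0.10,
                             fragment_radius_px = 1.6) {
  if (!inherits(optics, "optics_params")) {
    abort("`optics` must be created with optics_params().")
  }
  if (n_fibers < 1) abort("`n_fibers` must be >= 1.")
  subject <- as.list(as.data.frame(subject)[1, ])
  need <- c("mb_type1_mM", "mb_type2_mM", "pct_type1", "fcsa_type1_um2",
            "fcsa_type2_um2", "myonuclei_per_fiber", "satellites_per_fiber")
  if (!all(need %in% names(subject))) {
    abort(paste("`subject` must carry:", paste(need, collapse = ", ")))
  }

  ps_x <- optics$pixel_size
  ps_y <- optics$pixel_size * optics$pixel_aspect
  px_area <- ps_x * ps_y
  I0 <- optics$background_intensity
  maxval <- 2^optics$bit_depth - 1

  withr::with_seed(seed, {
    # fiber types and per-fiber geometry targets
    types <- ifelse(runif(n_fibers) < subject$pct_type1 / 100, "I", "II")
    fcsa_target <- ifelse(types == "I", subject$fcsa_type1_um2,
                          subject$fcsa_type2_um2)
    fcsa_target <- vapply(fcsa_target, function(m) {
      rtruncnorm(1, m, 0.2 * m, lower = m * 0.3)
    }, numeric(1))
    target_px <- fcsa_target / px_area

    H <- max(ceiling(sqrt(sum(target_px) / 0.92)), 120L)
    Wt <- max(ceiling(sum(target_px) / 0.92 / H), 40L)
    margin_w <- 28L

    lab_t <- voronoi_labels(H, Wt, n_fibers, weights = target_px)

    # fibers touching the tissue edge have truncated outlines
    edge_ids <- unique(c(lab_t[1, ], lab_t[H, ], lab_t[, 1], lab_t[, Wt]))

    # erode boundaries into a basal-lamina network (~4 px wide, so that
    # interstitial fragments fit between the laminas of adjacent fibers)
    bound <- dilate8(label_boundary(lab_t))
    lab_er <- lab_t
    lab_er[bound] <- 0L

    # full-size label map with margin
    W <- margin_w + Wt
    lab <- matrix(0L, H, W)
    lab[, (margin_w + 1):W] <- lab_er
    lamina <- matrix(FALSE, H, W)
    lamina[, (margin_w + 1):W] <- bound

    fiber_mask <- lab > 0L
    edge_mask <- fiber_mask & !erode8(fiber_mask)
    interior_mask <- erode8(erode8(fiber_mask))

    # per-fiber Mb concentration around the subject's type mean
    mb_mean <- ifelse(types == "I", subject$mb_type1_mM, subject$mb_type2_mM)
    mb_fiber <- vapply(mb_mean, function(m) {
      rtruncnorm(1, m, fiber_mb_cv * m, lower = 0)
    }, numeric(1))

    npx <- tabulate(lab[lab > 0L], nbins = n_fibers)
    rows_full <- matrix(rep(seq_len(H), W), H)
    cols_full <- matrix(rep(seq_len(W), each = H), H)

    fibers <- tibble(
      fiber_id = seq_len(n_fibers),
      fiber_type = types,
      mb_mM = mb_fiber,
      fcsa_um2 = npx * px_area,
      n_pixels = npx,
      border = seq_len(n_fibers) %in% edge_ids
    )

    # ---- nuclear fragments ---------------------------------------------------
    min_sep <- 2 * fragment_radius_px + 3
    placed <- matrix(numeric(0), 0, 2)
    frags <- list()
    fid <- 0L
    for (i in seq_len(n_fibers)) {
      sel_i <- lab == i
      edge_i <- which(sel_i & edge_mask)
      int_i <- which(sel_i & interior_mask)
      cand_edge <- cbind(rows_full[edge_i], cols_full[edge_i])
      cand_int <- cbind(rows_full[int_i], cols_full[int_i])

      k_myo <- rpois(1, subject$myonuclei_per_fiber)
      k_sat <- rpois(1, subject$satellites_per_fiber)
      k_cen <- rpois(1, central_rate * subject$myonuclei_per_fiber)

      for (cls in c("myonucleus", "satellite", "central")) {
        k <- switch(cls, myonucleus = k_myo, satellite = k_sat, central = k_cen)
        cand <- if (cls == "central") cand_int else cand_edge
        pts <- place_centers(cand, k, placed, min_sep)
        if (nrow(pts) > 0) {
          placed <- rbind(placed, pts)
          frags[[length(frags) + 1L]] <- tibble(
            fragment_id = fid + seq_len(nrow(pts)),
            fiber_id = i,
            row = pts[, 1], col = pts[, 2],
            class = cls,
            pax7_positive = cls == "satellite",
            touches_basal_lamina = cls != "central",
            inside_fiber = TRUE
          )
          fid <- fid + nrow(pts)
        }
      }
    }
    # interstitial fragments on the lamina core (between laminas), away from
    # fiber edges so the rendered blob does not overlap a fiber
    lam_idx <- which(erode8(lamina))
    cand_lam <- cbind(rows_full[lam_idx], cols_full[lam_idx])
    k_int <- rpois(1, interstitial_rate * subject$myonuclei_per_fiber * n_fibers)
    pts <- place_centers(cand_lam, k_int, placed, min_sep)
    if (nrow(pts) > 0) {
      placed <- rbind(placed, pts)
      frags[[length(frags) + 1L]] <- tibble(
        fragment_id = fid + seq_len(nrow(pts)),
        fiber_id = NA_integer_,
        row = pts[, 1], col = pts[, 2],
        class = "interstitial",
        pax7_positive = FALSE,
        touches_basal_lamina = TRUE,
        inside_fiber = FALSE
      )
    }
    fragments <- if (length(frags)) bind_rows(frags) else
      tibble(fragment_id = integer(), fiber_id = integer(), row = numeric(),
             col = numeric(), class = character(), pax7_positive = logical(),
             touches_basal_lamina = logical(), inside_fiber = logical())

    # ---- capillary spots -----------------------------------------------------
    spots <- list()
    spot_px <- list()
    sid <- 0L
    for (i in seq_len(n_fibers)) {
      k <- rpois(1, optics$capillary_spot_density)
      if (k < 1) next
      edge_i <- which(lab == i & edge_mask)
      if (!length(edge_i)) next
      centers <- sample(edge_i, min(k, length(edge_i)))
      for (ce in centers) {
        r0 <- rows_full[ce]; c0 <- cols_full[ce]
        off <- disk_offsets(fragment_radius_px)
        rr <- r0 + off[, 1]; cc <- c0 + off[, 2]
        keep <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
        lin <- as.integer((cc[keep] - 1L) * H + rr[keep])
        lin <- lin[lab[lin] == i]  # spot pixels inside this fiber only
        if (!length(lin)) next
        sid <- sid + 1L
        spots[[sid]] <- tibble(spot_id = sid, fiber_id = i,
                               row = r0, col = c0, n_pixels = length(lin))
        spot_px[[sid]] <- lin
      }
    }
    spots <- if (length(spots)) bind_rows(spots) else
      tibble(spot_id = integer(), fiber_id = integer(), row = numeric(),
             col = numeric(), n_pixels = integer())
    spots$pixels <- spot_px

    # ---- calibration blocks in the margin ------------------------------------
    concs <- optics$calibration_concentrations
    n_blk <- length(concs)
    blk_h <- max(10L, floor((H - 6L * (n_blk + 1L)) / n_blk))
    blk_h <- min(blk_h, 24L)
    blk_w <- margin_w - 8L
    gap <- floor((H - n_blk * blk_h) / (n_blk + 1L))
    calibration <- tibble(
      block_id = seq_len(n_blk),
      concentration_mM = concs,
      row0 = gap + (seq_len(n_blk) - 1L) * (blk_h + gap) + 1L,
      col0 = 5L
    )
    calibration$row1 <- calibration$row0 + blk_h - 1L
    calibration$col1 <- calibration$col0 + blk_w - 1L

    # ---- render channels -----------------------------------------------------
    od <- matrix(0, H, W)
    for (i in seq_len(n_fibers)) {
      od[lab == i] <- optics$extinction_scale * mb_fiber[i]
    }
    for (b in seq_len(n_blk)) {
      od[calibration$row0[b]:calibration$row1[b],
         calibration$col0[b]:calibration$col1[b]] <-
        optics$extinction_scale * concs[b]
    }
    for (lin in spot_px) od[lin] <- optics$capillary_spot_od

    quantize <- function(m) {
      if (optics$noise_sd > 0) m <- m + rnorm(length(m), 0, optics$noise_sd)
      matrix(pmin(pmax(round(m), 0), maxval), H, W)
    }
    transmission <- quantize(I0 * 10^(-od))

    mhc1 <- matrix(0, H, W); mhc2 <- matrix(0, H, W)
    for (i in seq_len(n_fibers)) {
      ch <- if (types[i] == "I") "mhc1" else "mhc2"
      if (ch == "mhc1") mhc1[lab == i] <- 200 else mhc2[lab == i] <- 200
    }
    wga <- matrix(0, H, W); wga[lamina] <- 255
    dapi <- matrix(0, H, W); pax7 <- matrix(0, H, W)
    if (nrow(fragments) > 0) {
      for (j in seq_len(nrow(fragments))) {
        st <- stamp_disk(dapi, fragments$row[j], fragments$col[j],
                         fragment_radius_px, 255)
        dapi <- st$m
        if (fragments$pax7_positive[j]) {
          pax7 <- stamp_disk(pax7, fragments$row[j], fragments$col[j],
                             fragment_radius_px, 255)$m
        }
      }
    }
    mhc1 <- quantize(mhc1); mhc2 <- quantize(mhc2)
    dapi <- quantize(dapi); pax7 <- quantize(pax7); wga <- quantize(wga)

    structure(list(
      channels = list(transmission = transmission, mhc1 = mhc1, mhc2 = mhc2,
                      dapi = dapi, pax7 = pax7, wga = wga),
      pixel_size = ps_x,
      pixel_aspect = optics$pixel_aspect,
      optics = optics,
      margin_cols = seq_len(margin_w),
      truth = list(label = lab, lamina = lamina, fibers = fibers,
                   fragments = fragments, spots = spots,
                   calibration = calibration),
      subject_id = subject$subject_id %||% NA_character_,
      seed = as.integer(seed)
    ), class = "muscle_section")
  })
}

#' @export
print.muscle_section <- function(x, ...) {
  d <- dim(x$channels$transmission)
  cat("<muscle_section> ", d[1], "x", d[2], " px (",
    round(d[1] * x$pixel_size * x$pixel_aspect), "x",
    round(d[2] * x$pixel_size), " um), ",
    nrow(x$truth$fibers), " fibers, ",
    nrow(x$truth$fragments), " nuclear fragments, ",
    nrow(x$truth$spots), " capillary spots\n",
    sep = ""
  )
  invisible(x)
}

#' Render a synthetic longitudinal section of elongated myonuclei
#'
#' Longitudinal sections are used only to measure average myonuclear length,
#' which feeds the stereological multiple-counting correction factor. Nuclei
#' are rendered as filled ellipses with major-axis lengths drawn from a
#' truncated normal at the stated moments (default 11 +/- 2 um) and random
#' orientations, placed on a grid so that no two nuclei touch.
#'
#' @param nuclear_length_mean_sd `c(mean, sd)` of the major-axis length (um).
#' @param n_nuclei Number of nuclei.
#' @param seed Integer seed.
#' @param pixel_size um/px of the rendered image.
#' @param minor_axis_um Minor-axis (width) of the rendered nuclei, um.
#' @return A `muscle_section` whose only informative channel is `dapi`; the
#'   ground truth table `truth$nuclei` records each drawn length.
#' @export
generate_longitudinal_section <- function(nuclear_length_mean_sd = c(11, 2),
                                          n_nuclei = 100,
                                          seed = 1L,
                                          pixel_size = 0.5,
                                          minor_axis_um = 3) {
  check_moments(nuclear_length_mean_sd, "nuclear_length_mean_sd")
  if (n_nuclei < 1) abort("`n_nuclei` must be >= 1.")
  withr::with_seed(seed, {
    len <- rtruncnorm(n_nuclei, nuclear_length_mean_sd[1],
                      nuclear_length_mean_sd[2], lower = 2)
    ang <- runif(n_nuclei, 0, pi)
    cell_px <- ceiling((max(len) + 6) / pixel_size)
    n_side <- ceiling(sqrt(n_nuclei))
    H <- W <- n_side * cell_px
    dapi <- matrix(0, H, W)
    cy <- cx <- numeric(n_nuclei)
    for (j in seq_len(n_nuclei)) {
      gi <- (j - 1) %/% n_side
      gj <- (j - 1) %% n_side
      cy[j] <- gi * cell_px + cell_px / 2
      cx[j] <- gj * cell_px + cell_px / 2
      a <- len[j] / 2 / pixel_size
      b <- minor_axis_um / 2 / pixel_size
      half <- ceiling(a) + 1L
      rr <- max(1, floor(cy[j] - half)):min(H, ceiling(cy[j] + half))
      cc <- max(1, floor(cx[j] - half)):min(W, ceiling(cx[j] + half))
      dy <- outer(rr - cy[j], rep(1, length(cc)))
      dx <- outer(rep(1, length(rr)), cc - cx[j])
      u <- (dx * cos(ang[j]) + dy * sin(ang[j])) / a
      v <- (-dx * sin(ang[j]) + dy * cos(ang[j])) / b
      inside <- u^2 + v^2 <= 1
      blk <- dapi[rr, cc]
      blk[inside] <- 255
      dapi[rr, cc] <- blk
    }
    structure(list(
      channels = list(dapi = dapi),
      pixel_size = pixel_size,
      pixel_aspect = 1,
      optics = NULL,
      margin_cols = integer(),
      truth = list(nuclei = tibble(nucleus_id = seq_len(n_nuclei),
                                   length_um = len, angle = ang,
                                   row = cy, col = cx)),
      subject_id = NA_character_,
      seed = as.integer(seed)
    ), class = "muscle_section")
  })
}
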
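#' Area and perimeter of a fiber outline polygon
#'
#' Shoelace area (absolute value) and Euclidean perimeter of a simple closed
#' polygon. Coordinates are taken in um; if given in pixels, supply
#' `pixel_size` (and `pixel_aspect` for non-square pixels) to scale x by
#' `pixel_size` and y by `pixel_size * pixel_aspect` before any geometry.
#'
#' @param outline Two-column matrix or data frame of vertices (`x`, `y`),
#'   open or closed (first vertex need not be repeated).
#' @param pixel_size Scale factor applied to both axes (um/px); 1 when the
#'   outline is already in um.
#' @param pixel_aspect Pixel height/width ratio applied to y.
#' @return One-row tibble with `fcsa_um2` and `perimeter_um`.
#' @examples
#' sq <- cbind(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1))
#' polygon_area_perimeter(sq)  # area 1, perimeter 4
#' @export
polygon_area_perimeter <- function(outline, pixel_size = 1, pixel_aspect = 1) {
  m <- as.matrix(outline[, 1:2])
  storage.mode(m) <- "double"
  # drop an explicitly repeated closing vertex
  if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
  if (nrow(m) < 3) abort("A polygon needs >= 3 vertices.")
  x <- m[, 1] * pixel_size
  y <- m[, 2] * pixel_size * pixel_aspect
  xs <- c(x[-1], x[1])
  ys <- c(y[-1], y[1])
  area <- abs(sum(x * ys - xs * y)) / 2
  if (area <= 0) abort("Degenerate (zero-area) polygon.")
  per <- sum(sqrt((xs - x)^2 + (ys - y)^2))
  tibble(fcsa_um2 = area, perimeter_um = per)
}

#' Fiber circularity
#'
#' `circularity = 4 * pi * FCSA / perimeter^2`: 1 for a circle (isoperimetric
#' equality), lower for irregular outlines.
#'
#' @param fcsa Area(s), um^2, > 0.
#' @param perimeter Perimeter(s), um, > 0.
#' @return Dimensionless circularity, vectorized.
#' @examples
#' circularity(1, 4)      # unit square: pi/4
#' circularity(pi, 2 * pi)  # unit circle: 1
#' @export
circularity <- function(fcsa, perimeter) {
  if (any(fcsa <= 0) || any(perimeter <= 0)) {
    abort("`fcsa` and `perimeter` must be > 0.")
  }
  4 * pi * fcsa / perimeter^2
}

#' Apply the circularity exclusion filter
#'
#' Fibers with circularity at or below the cutoff (default 0.60) are flagged
#' as excluded rather than dropped: the `included` column records the
#' decision and downstream morphometric and stereological statistics use
#' only included fibers.
#'
#' @param records Tibble with a `circularity` column.
#' @param cutoff Exclusion cutoff; a fiber is kept only when
#'   `circularity > cutoff` (a fiber at exactly the cutoff is excluded).
#' @return `records` with (re)computed logical `included`.
#' @export
filter_circular_fibers <- function(records, cutoff = 0.60) {
  stopifnot(is.data.frame(records))
  if (!"circularity" %in% names(records)) {
    abort("`records` must carry a circularity column.")
  }
  mutate(records, included = .data$circularity > cutoff)
}

#' Extract sub-pixel fiber outlines from a label map
#'
#' Traces each fiber's boundary with marching-squares contouring
#' ([grDevices::contourLines()] at level 0.5 on the fiber's indicator
#' image), which cuts pixel corners diagonally and avoids the perimeter
#' inflation of pixel-edge tracing. Coordinates are returned in um, with the
#' pixel aspect ratio applied.
#'
#' @param section A `muscle_section`.
#' @param fiber_ids Fibers to trace (default all).
#' @return Tibble with `fiber_id`, `vertex`, `x_um`, `y_um`.
#' @export
fiber_outlines <- function(section, fiber_ids = NULL) {
  stopifnot(inherits(section, "muscle_section"))
  lab <- section$truth$label
  fiber_ids <- fiber_ids %||% sort(unique(lab[lab > 0L]))
  ps_x <- section$pixel_size
  ps_y <- section$pixel_size * section$pixel_aspect
  purrr::map_dfr(fiber_ids, function(i) {
    ind <- (lab == i) * 1
    cl <- contourLines(x = seq_len(nrow(ind)) * ps_y,
                       y = seq_len(ncol(ind)) * ps_x,
                       z = ind, levels = 0.5)
    if (!length(cl)) return(NULL)
    main <- cl[[which.max(vapply(cl, function(s) length(s$x), numeric(1)))]]
    tibble(fiber_id = i, vertex = seq_along(main$x),
           x_um = main$y, y_um = main$x)
  })
}

#' Assign a fiber type from the MHC channels
#'
#' The fiber is typed by whichever myosin-heavy-chain channel has the larger
#' background-subtracted median intensity over the fiber region; when both
#' exceed the positivity threshold and differ by less than 20% the fiber is
#' called hybrid (double-positive).
#'
#' @param mhc1_px,mhc2_px Pixel intensities of the two MHC channels inside
#'   the fiber region.
#' @param background1,background2 Channel background levels to subtract.
#' @param positive_threshold Background-subtracted median above which a
#'   channel counts as positive.
#' @param hybrid_tol Relative difference below which a double-positive fiber
#'   is called hybrid.
#' @return One of `"I"`, `"II"`, `"hybrid"`.
#' @export
assign_fiber_type <- function(mhc1_px, mhc2_px,
                              background1 = 0, background2 = 0,
                              positive_threshold = 50,
                              hybrid_tol = 0.2) {
  if (!length(mhc1_px) || !length(mhc2_px)) abort("Empty fiber region.")
  m1 <- median(mhc1_px) - background1
  m2 <- median(mhc2_px) - background2
  if (m1 > positive_threshold && m2 > positive_threshold &&
      abs(m1 - m2) < hybrid_tol * max(m1, m2)) {
    return("hybrid")
  }
  if (m1 >= m2) "I" else "II"
}

#' Fiber-type distribution
#'
#' Percentages of type I and type II fibers over all typed fibers. Hybrid
#' (double-positive) fibers are pooled into type II by default, matching a
#' two-class reporting convention with a type II antibody that does not
#' resolve subtypes; set `hybrid_as` to change this. Percentages sum to 100.
#'
#' @param fiber_type Character vector of `"I"` / `"II"` / `"hybrid"`.
#' @param hybrid_as Class hybrids count toward (`"II"` or `"I"`).
#' @return One-row tibble with `pct_type1`, `pct_type2`, `n_typed`.
#' @export
fiber_type_distribution <- function(fiber_type, hybrid_as = c("II", "I")) {
  hybrid_as <- match.arg(hybrid_as)
  fiber_type <- fiber_type[!is.na(fiber_type)]
  if (!length(fiber_type)) abort("No typed fibers.")
  ft <- ifelse(fiber_type == "hybrid", hybrid_as, fiber_type)
  n1 <- sum(ft == "I")
  tibble(pct_type1 = 100 * n1 / length(ft),
         pct_type2 = 100 * (length(ft) - n1) / length(ft),
         n_typed = length(ft))
}

#' Morphometry of all fibers in a section
#'
#' Traces outlines, computes FCSA, perimeter and circularity per fiber,
#' flags border-touching fibers (truncated outlines bias area and
#' circularity), applies the circularity filter, and types each fiber from
#' the MHC channels.
#'
#' @param section A `muscle_section`.
#' @param cutoff Circularity exclusion cutoff.
#' @return Tibble with one row per fiber: `fiber_id`, `fcsa_um2`,
#'   `perimeter_um`, `circularity`, `border`, `included`, `fiber_type`.
#'   `included` is `circularity > cutoff` and not border-touching.
#' @export
measure_morphometry <- function(section, cutoff = 0.60) {
  stopifnot(inherits(section, "muscle_section"))
  lab <- section$truth$label
  outlines <- fiber_outlines(section)
  geom <- outlines |>
    group_by(.data$fiber_id) |>
    summarise(polygon_area_perimeter(cbind(.data$x_um, .data$y_um)),
              .groups = "drop")
  border_ids <- section$truth$fibers$fiber_id[section$truth$fibers$border]
  m1 <- section$channels$mhc1
  m2 <- section$channels$mhc2
  bg1 <- median(m1[lab == 0L])
  bg2 <- median(m2[lab == 0L])
  geom |>
    mutate(
      circularity = circularity(.data$fcsa_um2, .data$perimeter_um),
      border = .data$fiber_id %in% border_ids,
      fiber_type = vapply(.data$fiber_id, function(i) {
        assign_fiber_type(m1[lab == i], m2[lab == i], bg1, bg2)
      }, character(1))
    ) |>
    filter_circular_fibers(cutoff = cutoff) |>
    mutate(included = .data$included & !.data$border)
}
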
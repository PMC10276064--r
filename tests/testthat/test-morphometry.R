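test_that("polygon area and perimeter match closed forms", {
  sq <- cbind(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1))
  g <- polygon_area_perimeter(sq)
  expect_equal(g$fcsa_um2, 1)
  expect_equal(g$perimeter_um, 4)

  tri <- cbind(x = c(0, 3, 0), y = c(0, 0, 4))
  g <- polygon_area_perimeter(tri)
  expect_equal(g$fcsa_um2, 6)
  expect_equal(g$perimeter_um, 12)

  gon <- regular_polygon(64, r = 50)
  g <- polygon_area_perimeter(gon)
  expect_lt(abs(g$fcsa_um2 - pi * 50^2) / (pi * 50^2), 0.002)

  # pixel size and aspect scale the geometry before measurement
  g2 <- polygon_area_perimeter(sq, pixel_size = 2, pixel_aspect = 1.5)
  expect_equal(g2$fcsa_um2, 2 * 3)
  expect_equal(g2$perimeter_um, 2 * (2 + 3))

  expect_error(polygon_area_perimeter(cbind(c(0, 1), c(0, 1))), "vertices")
  expect_error(polygon_area_perimeter(cbind(c(0, 1, 2), c(0, 1, 2))),
               "Degenerate")
})

test_that("circularity matches isoperimetric closed forms", {
  expect_equal(circularity(pi * 4, 2 * pi * 2), 1)       # circle, r = 2
  expect_equal(circularity(1, 4), pi / 4)                 # unit square
  hex <- polygon_area_perimeter(regular_polygon(6, 1))
  expect_equal(circularity(hex$fcsa_um2, hex$perimeter_um), pi * sqrt(3) / 6,
               tolerance = 1e-12)
  expect_error(circularity(0, 4), "> 0")
})

test_that("circularity never exceeds 1 and is rigid-motion invariant", {
  withr::with_seed(21, {
    for (k in 1:50) {
      n <- sample(5:40, 1)
      th <- sort(runif(n, 0, 2 * pi))
      r <- runif(n, 0.5, 2)
      poly <- cbind(x = r * cos(th), y = r * sin(th))  # star-shaped, simple
      g <- polygon_area_perimeter(poly)
      expect_lte(circularity(g$fcsa_um2, g$perimeter_um), 1 + 1e-9)

      # rotation + translation leave area/perimeter unchanged
      a <- runif(1, 0, 2 * pi)
      R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2)
      moved <- sweep(poly %*% R, 2, runif(2, -5, 5), `+`)
      g2 <- polygon_area_perimeter(moved)
      expect_equal(g2$fcsa_um2, g$fcsa_um2, tolerance = 1e-9)
      expect_equal(g2$perimeter_um, g$perimeter_um, tolerance = 1e-9)

      # uniform scaling s: area ~ s^2, perimeter ~ s
      s <- runif(1, 0.5, 3)
      g3 <- polygon_area_perimeter(poly * s)
      expect_equal(g3$fcsa_um2, g$fcsa_um2 * s^2, tolerance = 1e-9)
      expect_equal(g3$perimeter_um, g$perimeter_um * s, tolerance = 1e-9)
    }
  })
})

test_that("the circularity filter excludes the 0.60 boundary and is idempotent", {
  rec <- tibble::tibble(fiber_id = 1:4,
                        circularity = c(0.60, 0.601, 1.0, 0.3))
  f1 <- filter_circular_fibers(rec)
  expect_equal(f1$included, c(FALSE, TRUE, TRUE, FALSE))
  expect_identical(filter_circular_fibers(f1), f1)
  expect_equal(nrow(f1), 4)  # exclusion is recorded, not deleted

  # a 2:1 ellipse passes the filter; Ramanujan perimeter as the oracle
  a <- 2; b <- 1
  per_r <- pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))
  circ_r <- circularity(pi * a * b, per_r)
  expect_equal(circ_r, 0.84, tolerance = 0.01)
  g <- polygon_area_perimeter(ellipse_polygon(a, b))
  expect_equal(circularity(g$fcsa_um2, g$perimeter_um), circ_r,
               tolerance = 1e-3)
  expect_gt(circ_r, 0.60)
})

test_that("fiber typing follows the dominant MHC channel", {
  expect_equal(assign_fiber_type(rep(200, 9), rep(0, 9)), "I")
  expect_equal(assign_fiber_type(rep(0, 9), rep(200, 9)), "II")
  expect_equal(assign_fiber_type(rep(200, 9), rep(190, 9)), "hybrid")
  expect_equal(assign_fiber_type(rep(200, 9), rep(100, 9)), "I")
  expect_error(assign_fiber_type(numeric(0), numeric(0)), "Empty")
})

test_that("zero-noise section types and typed percentages match truth", {
  sec <- demo_section()
  m <- measure_morphometry(sec)
  truth <- sec$truth$fibers
  joined <- dplyr::left_join(m, truth, by = "fiber_id")
  expect_equal(joined$fiber_type.x, joined$fiber_type.y)

  dist <- fiber_type_distribution(m$fiber_type)
  truth_dist <- fiber_type_distribution(truth$fiber_type)
  expect_equal(dist$pct_type1, truth_dist$pct_type1)
  expect_equal(dist$pct_type1 + dist$pct_type2, 100)

  # all measured circularities are physical and border fibers are flagged
  expect_true(all(m$circularity > 0 & m$circularity <= 1.02))
  expect_true(any(m$border))
  expect_true(all(!m$included[m$border]))
})

test_that("fiber-type distribution arithmetic and hybrid pooling", {
  expect_equal(fiber_type_distribution(rep("I", 10))$pct_type1, 100)
  ft <- c(rep("I", 132), rep("II", 68))
  d <- fiber_type_distribution(ft)
  expect_equal(d$pct_type1, 66.0)
  expect_equal(d$pct_type2, 34.0)
  dh <- fiber_type_distribution(c("I", "hybrid", "II", "II"))
  expect_equal(dh$pct_type1, 25)
  dh2 <- fiber_type_distribution(c("I", "hybrid", "II", "II"),
                                 hybrid_as = "I")
  expect_equal(dh2$pct_type1, 50)
  expect_error(fiber_type_distribution(character(0)), "No typed")
})
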
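rect <- aperture_polygon(c(-3, 3, 3, -3), c(-1, -1, 1, 1))

test_that("polygon construction validates shape, orientation and simplicity", {
  expect_equal(polygon_area(rect), 12)
  # clockwise input is reoriented, closing vertex dropped
  cw <- aperture_polygon(c(-1, -1, 1, 1, -1), c(-1, 1, 1, -1, -1))
  expect_equal(polygon_area(cw), 4)
  expect_error(aperture_polygon(c(0, 1), c(0, 1)), "3 distinct")
  expect_error(aperture_polygon(c(0, 1, 2), c(0, 0, 0)), "degenerate")
  expect_error(aperture_polygon(c(0, 4, 4, 1, 0), c(0, 0, 3, -1, 3)),
               "self-intersecting")
})

test_that("leaf-aligned rectangles are fitted exactly with zero area error", {
  bank <- fit_leaf_positions(rect, leaf_width = 0.5)
  expect_equal(nrow(bank), 4)
  expect_true(all(bank$open))
  expect_true(all(bank$left_tip == -3))
  expect_true(all(bank$right_tip == 3))
  expect_equal(aperture_area_error(rect, bank), 0, tolerance = 1e-12)
})

test_that("circle tips follow the closed-form chord half-width", {
  r <- 2.5
  theta <- 2 * pi * (0:255) / 256
  circ <- aperture_polygon(r * cos(theta), r * sin(theta))
  bank <- fit_leaf_positions(circ, leaf_width = 0.5)
  y_mid <- (bank$row_min + bank$row_max) / 2
  half <- sqrt(pmax(0, r^2 - y_mid^2))
  # polygonized circle: vertex chords sit within O(r * dtheta^2) of the circle
  expect_equal(bank$right_tip, half, tolerance = 2e-3)
  expect_equal(bank$left_tip, -half, tolerance = 2e-3)
})

test_that("midpoint rule puts every open tip exactly on the polygon boundary", {
  on_boundary <- function(poly, x, y, tol = 1e-9) {
    v <- unclass(poly)
    n <- nrow(v)
    v2 <- v[c(2:n, 1), , drop = FALSE]
    any(vapply(seq_len(n), function(e) {
      dx <- v2[e, 1] - v[e, 1]; dy <- v2[e, 2] - v[e, 2]
      len2 <- dx^2 + dy^2
      t <- ((x - v[e, 1]) * dx + (y - v[e, 2]) * dy) / len2
      t >= -tol & t <= 1 + tol &
        abs((x - v[e, 1]) * dy - (y - v[e, 2]) * dx) / sqrt(len2) <= tol
    }, logical(1)))
  }
  for (seed in 1:15) {
    poly <- synth_convex_polygon(seed)
    bank <- fit_leaf_positions(poly, leaf_width = 0.5)
    op <- bank[bank$open, ]
    mid <- (op$row_min + op$row_max) / 2
    for (i in seq_len(nrow(op))) {
      expect_true(on_boundary(poly, op$left_tip[i], mid[i]))
      expect_true(on_boundary(poly, op$right_tip[i], mid[i]))
    }
  }
})

test_that("a polygon confined to one row opens a single leaf", {
  small <- aperture_polygon(c(0, 1, 0.5), c(0.05, 0.05, 0.4))
  bank <- fit_leaf_positions(small, leaf_width = 0.5)
  expect_equal(sum(bank$open), 1)
})

test_that("open leaves cover the midline chords of convex polygons", {
  for (seed in 1:10) {
    poly <- synth_convex_polygon(seed)
    bank <- fit_leaf_positions(poly, leaf_width = 0.5)
    op <- bank[bank$open, ]
    mid <- (op$row_min + op$row_max) / 2
    # sample interior points of each midline chord; all must be in the leaf
    for (i in seq_len(nrow(op))) {
      xs <- seq(op$left_tip[i], op$right_tip[i], length.out = 9)
      expect_true(all(xs >= op$left_tip[i] - 1e-9 &
                      xs <= op$right_tip[i] + 1e-9))
      inside <- point_in_polygon(xs[2:8], rep(mid[i], 7), poly)
      expect_true(all(inside))
    }
  }
})

test_that("quadrature area error matches the rasterization oracle within 1%", {
  circ <- synth_aperture(1, mean_radius = 2.5, irregularity = 0)
  bank <- fit_leaf_positions(circ, leaf_width = 0.5)
  q <- aperture_area_error(circ, bank)
  o <- rasterize_area_error(circ, bank, cell = 0.01)
  expect_equal(q, o, tolerance = 0.01)
  for (seed in c(3, 8)) {
    poly <- synth_convex_polygon(seed)
    b2 <- fit_leaf_positions(poly, leaf_width = 0.5)
    expect_equal(aperture_area_error(poly, b2),
                 rasterize_area_error(poly, b2, cell = 0.01),
                 tolerance = 0.01)
  }
})

test_that("halving the leaf width never increases the error for convex polygons", {
  widths <- c(1, 0.5, 0.25, 0.125)
  for (seed in 1:25) {
    poly <- synth_convex_polygon(seed)
    errs <- vapply(widths, function(w)
      aperture_area_error(poly, fit_leaf_positions(poly, w)), numeric(1))
    expect_true(all(diff(errs) <= 1e-9))
    expect_lt(errs[length(errs)], errs[1] + 1e-9)
  }
})

test_that("orientation variants agree for symmetric apertures", {
  sq <- aperture_polygon(c(-2, 2, 2, -2), c(-2, -2, 2, 2))
  both <- orientation_variants(sq, leaf_width = 0.5)
  expect_equal(both$y$area_error, 0, tolerance = 1e-12)
  expect_equal(both$x$area_error, 0, tolerance = 1e-12)
  circ <- synth_aperture(1, irregularity = 0)
  bc <- orientation_variants(circ, leaf_width = 0.5)
  expect_equal(bc$y$area_error, bc$x$area_error, tolerance = 0.02)
  # 2:1 ellipse: both orientations produce finite, positive errors
  th <- 2 * pi * (0:127) / 128
  ell <- aperture_polygon(3 * cos(th), 1.5 * sin(th))
  be <- orientation_variants(ell, leaf_width = 0.5)
  expect_gt(be$y$area_error, 0)
  expect_gt(be$x$area_error, 0)
})

test_that("polygon and leaf-bank CSV I/O round-trip", {
  poly <- synth_convex_polygon(5)
  p <- withr::local_tempfile(fileext = ".csv")
  write_polygon_csv(poly, p)
  back <- read_polygon_csv(p)
  expect_equal(unclass(back), unclass(poly), ignore_attr = TRUE)
  bank <- fit_leaf_positions(poly, 0.5)
  b <- withr::local_tempfile(fileext = ".csv")
  write_leaf_bank_csv(bank, b)
  reread <- read.csv(b)
  expect_equal(reread$left_tip, bank$left_tip)
  expect_equal(reread$open, bank$open)
})
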
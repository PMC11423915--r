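test_that("area and perimeter match closed forms on simple shapes", {
  sq <- cell_contour(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
  expect_equal(polygon_area(sq), 1)
  expect_equal(polygon_perimeter(sq), 4)

  tri <- cell_contour(cbind(c(0, 4, 0), c(0, 0, 3)))
  expect_equal(polygon_area(tri), 6)
  expect_equal(polygon_perimeter(tri), 12)  # 3-4-5 right triangle

  # regular hexagon of circumradius 2: perimeter n * 2R * sin(pi/n)
  n <- 6; R <- 2
  ang <- 2 * pi * (0:(n - 1)) / n
  hex <- cell_contour(cbind(R * cos(ang), R * sin(ang)))
  expect_equal(polygon_perimeter(hex), n * 2 * R * sin(pi / n))

  expect_error(cell_contour(cbind(c(0, 1, 2), c(0, 1, 2))), "degenerate")
})

test_that("area of random simple polygons agrees with the Monte Carlo oracle", {
  set.seed(101)
  for (rep in 1:3) {
    v <- random_star_polygon(12)
    mc <- oracle_mc_area(v, 1e6)
    expect_lt(abs(polygon_area(v) - mc$estimate), 3 * mc$se)
  }
})

test_that("convex hull is convex, tight, and matches the brute-force oracle", {
  # a convex polygon is its own hull
  sq <- cell_contour(cbind(c(0, 2, 2, 0), c(0, 0, 2, 2)))
  h <- convex_hull(sq)
  expect_equal(polygon_area(h), 4)
  expect_equal(nrow(h$vertices), 4L)

  # an interior point disappears
  withpt <- rbind(c(0, 0), c(2, 0), c(1, 1), c(2, 2), c(0, 2))
  h2 <- convex_hull(cell_contour(withpt))
  expect_equal(polygon_area(h2), 4)
  expect_equal(nrow(h2$vertices), 4L)

  set.seed(7)
  for (rep in 1:5) {
    pts <- matrix(runif(100, -3, 3), ncol = 2)
    h <- convex_hull(pts)
    expect_setequal(
      apply(round(h$vertices, 9), 1, paste, collapse = ","),
      apply(round(pts[oracle_hull_indices(pts), ], 9), 1, paste,
            collapse = ","))
  }
})

test_that("rotating-calipers MBR matches trivial cases and is rigid-motion equivariant", {
  r21 <- cell_contour(cbind(c(0, 2, 2, 0), c(0, 0, 1, 1)))
  m <- min_bounding_rectangle(r21)
  expect_equal(m$length, 2)
  expect_equal(m$width, 1)
  expect_equal(m$angle, 0)

  rot <- cell_contour(rot2(r21$vertices, pi / 6))
  m30 <- min_bounding_rectangle(rot)
  expect_equal(m30$length, 2)
  expect_equal(m30$width, 1)
  expect_equal(m30$angle, pi / 6, tolerance = 1e-9)
})

test_that("MBR area equals the dense angle-sweep oracle on random convex polygons", {
  set.seed(11)
  for (rep in 1:10) {
    v <- random_convex_polygon(10)
    m <- min_bounding_rectangle(v)
    sweep_area <- oracle_mbr_sweep_area(v, 1e5)
    expect_lt(abs(m$length * m$width - sweep_area) / sweep_area, 1e-6)
    # the sweep can only be larger or equal up to grid resolution
    expect_lte(m$length * m$width, sweep_area + 1e-9)
  }
})

test_that("rectangularity is 1 exactly for rectangles, < 1 otherwise, and matches MC", {
  rect <- cell_contour(cbind(c(0, 10, 10, 0), c(0, 0, 4, 4)))
  expect_equal(rectangularity(rect), 1, tolerance = 1e-9)
  rot <- cell_contour(translate2(rot2(rect$vertices, 0.7), 3, 3))
  expect_equal(rectangularity(rot), 1, tolerance = 1e-9)

  # parallelogram with 45 degree interior angle, base 4, side 2
  s <- 2 / sqrt(2)
  par <- cell_contour(cbind(c(0, 4, 4 + s, s), c(0, 0, s, s)))
  r_par <- rectangularity(par)
  expect_lt(r_par, 1)
  mbr <- min_bounding_rectangle(convex_hull(par))
  k <- sqrt(polygon_area(par) / (mbr$length * mbr$width))
  u <- c(cos(mbr$angle), sin(mbr$angle)); w <- c(-u[2], u[1])
  corners <- rbind(mbr$centre - k * (mbr$length / 2) * u - k * (mbr$width / 2) * w,
                   mbr$centre + k * (mbr$length / 2) * u - k * (mbr$width / 2) * w,
                   mbr$centre + k * (mbr$length / 2) * u + k * (mbr$width / 2) * w,
                   mbr$centre - k * (mbr$length / 2) * u + k * (mbr$width / 2) * w)
  set.seed(21)
  mc <- oracle_mc_intersection(par$vertices, corners, 1e6)
  expect_lt(abs(r_par - mc$estimate / polygon_area(par)),
            3 * mc$se / polygon_area(par))

  tri <- cell_contour(cbind(c(0, 3, 0), c(0, 0, 4)))
  r_tri <- rectangularity(tri)
  expect_lt(r_tri, 1)
})

test_that("descriptors are invariant under rigid motions and equivariant under scaling", {
  set.seed(33)
  v <- random_star_polygon(10)
  cc <- cell_contour(v)
  base <- list(a = polygon_area(cc), p = polygon_perimeter(cc),
               e = {
                 m <- min_bounding_rectangle(convex_hull(cc))
                 m$length / m$width
               },
               r = rectangularity(cc))
  for (theta in c(0.3, 1.2, 2.9)) {
    moved <- cell_contour(translate2(rot2(v, theta), 5, -2))
    m <- min_bounding_rectangle(convex_hull(moved))
    expect_equal(polygon_area(moved), base$a, tolerance = 1e-9)
    expect_equal(polygon_perimeter(moved), base$p, tolerance = 1e-9)
    expect_equal(m$length / m$width, base$e, tolerance = 1e-9)
    expect_equal(rectangularity(moved), base$r, tolerance = 1e-7)
  }
  s <- 3.7
  scaled <- cell_contour(v * s)
  m <- min_bounding_rectangle(convex_hull(scaled))
  expect_equal(polygon_area(scaled), base$a * s^2, tolerance = 1e-9)
  expect_equal(polygon_perimeter(scaled), base$p * s, tolerance = 1e-9)
  expect_equal(m$length / m$width, base$e, tolerance = 1e-9)
  expect_equal(rectangularity(scaled), base$r, tolerance = 1e-7)
})

test_that("area <= hull area <= MBR area for every cell", {
  set.seed(55)
  for (rep in 1:10) {
    v <- random_star_polygon(14)
    cc <- cell_contour(v)
    h <- convex_hull(cc)
    m <- min_bounding_rectangle(h)
    expect_lte(polygon_area(cc), polygon_area(h) + 1e-9)
    expect_lte(polygon_area(h), m$length * m$width + 1e-9)
  }
})

test_that("cell_morphometrics returns one valid record per cell", {
  g <- generate_lamina(3, 3, cell_size = 5)
  cm <- cell_morphometrics(g$lamina)
  expect_equal(nrow(cm), 9L)
  expect_equal(cm$elongation, rep(1, 9))
  expect_equal(cm$rectangularity, rep(1, 9), tolerance = 1e-9)
  expect_equal(cm$area_um2, rep(25, 9))
  expect_true(all(cm$area_um2 <= cm$hull_area_um2 + 1e-9))
  expect_true(all(cm$hull_area_um2 <=
                    cm$mbr_length_um * cm$mbr_width_um + 1e-9))

  gj <- generate_lamina(5, 5, cell_size = 5, jitter = 0.3, seed = 9)
  cmj <- cell_morphometrics(gj$lamina)
  expect_lt(mean(cmj$rectangularity), 1)

  # degeneracy is reported with the cell id
  lam <- g$lamina
  lam$cells[[4]]$vertices <- cbind(c(0, 1, 2), c(0, 1, 2))
  expect_error(cell_morphometrics(lam), lam$cells[[4]]$cell_id)
})
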
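test_that("jitter-0 grids are exact rectangles matching their ground truth", {
  g <- generate_lamina(rows = 8, cols = 1, cell_size = 8)
  expect_equal(n_cells(g$lamina), 8L)
  expect_equal(g$truth$blade$main_axis_length, 64)
  expect_equal(g$truth$blade$secondary_axis_length, 8)
  expect_equal(g$truth$blade$lw_ratio, 8)
  ax <- blade_axes(g$lamina)
  expect_equal(ax$main_axis_length, g$truth$blade$main_axis_length,
               tolerance = 1e-9)
  expect_equal(ax$secondary_axis_length, g$truth$blade$secondary_axis_length,
               tolerance = 1e-9)

  g6 <- generate_lamina(6, 6, cell_size = 5)
  counts <- neighbour_counts(neighbour_graph(g6$lamina))
  expect_equal(sum(counts == 4L), 16L)
  expect_equal(sum(counts == 3L), 16L)
  expect_equal(sum(counts == 2L), 4L)

  # analysis outputs equal analytic ground truth on the exact grid
  cm <- cell_morphometrics(g6$lamina)
  tr <- g6$truth$cells
  expect_equal(cm$area_um2, tr$area_um2, tolerance = 1e-9)
  expect_equal(cm$perimeter_um, tr$perimeter_um, tolerance = 1e-9)
  expect_equal(cm$elongation, tr$elongation, tolerance = 1e-9)
  expect_equal(cm$rectangularity, tr$rectangularity, tolerance = 1e-9)
  expect_equal(blade_area(g6$lamina), g6$truth$blade$area_um2,
               tolerance = 1e-6)
})

test_that("generated laminae are deterministic: same seed, byte-identical SVG", {
  f1 <- tempfile(fileext = ".svg"); f2 <- tempfile(fileext = ".svg")
  write_lamina_svg(generate_lamina(5, 4, jitter = 0.3, seed = 99)$lamina, f1)
  write_lamina_svg(generate_lamina(5, 4, jitter = 0.3, seed = 99)$lamina, f2)
  expect_identical(readLines(f1), readLines(f2))
  f3 <- tempfile(fileext = ".svg")
  write_lamina_svg(generate_lamina(5, 4, jitter = 0.3, seed = 100)$lamina, f3)
  expect_false(identical(readLines(f1), readLines(f3)))
})

test_that("jitter degrades rectangularity in paired comparisons across seeds", {
  worse <- vapply(1:20, function(seed) {
    gj <- generate_lamina(10, 10, cell_size = 6, jitter = 0.3, seed = seed)
    mean(cell_morphometrics(gj$lamina)$rectangularity)
  }, numeric(1))
  g0 <- generate_lamina(10, 10, cell_size = 6, jitter = 0)
  base <- mean(cell_morphometrics(g0$lamina)$rectangularity)
  expect_true(all(worse < base))
  expect_lt(mean(worse), 1)
})

test_that("generator rejects invalid specifications", {
  expect_error(generate_lamina(0, 3), "positive integers")
  expect_error(generate_lamina(3, 3, jitter = 0.5), "0, 0.5")
  expect_error(generate_lamina(3, 3, cell_size = -1), "positive")
  expect_error(generate_lamina(3, 3, elongation_target = 0.5), ">= 1")
})

test_that("division rules: first division transverse; onset gates longitudinal", {
  sim <- simulate_division_growth("intact", n_target_cells = 8, seed = 1)
  expect_equal(sim$events$orientation, rep("transverse", 7))
  # the 8-cell intact embryo is a 1 x 8 stack
  bm <- blade_metrics(sim$snapshots[["8"]])
  expect_equal(bm$lw_ratio, 8, tolerance = 1e-9)

  sv <- simulate_division_growth("severed", n_target_cells = 8, seed = 2)
  expect_equal(sv$events$orientation[1], "transverse")
  expect_true("longitudinal" %in% sv$events$orientation)

  # no oblique planes are ever generated
  big <- simulate_division_growth("intact", n_target_cells = 60, seed = 3)
  expect_true(all(big$events$orientation %in%
                    c("transverse", "longitudinal")))
  # counts are non-decreasing and integer
  expect_true(all(diff(big$series$n_cells) >= 0))
  expect_equal(big$series$n_cells, round(big$series$n_cells))
})

test_that("the emitted growth series flags t0 at the first longitudinal division", {
  sim <- simulate_division_growth("intact", n_target_cells = 40, seed = 5)
  expect_false(is.na(sim$t0_h))
  idx <- sim$series$t0_index
  expect_gte(sim$series$time_h[idx], sim$t0_h)
  if (idx > 1) expect_lt(sim$series$time_h[idx - 1], sim$t0_h)
  first_long <- sim$events$time_h[sim$events$orientation == "longitudinal"][1]
  expect_equal(sim$t0_h, first_long)
})

test_that("division-simulated growth recovers ~26 h doubling at default cycle spread", {
  taus <- vapply(1:10, function(seed) {
    sim <- simulate_division_growth("intact", n_target_cells = 120,
                                    seed = seed)
    fit_growth_rate(sim$series)$doubling_time_h
  }, numeric(1))
  expect_lt(abs(mean(taus) - 26) / 26, 0.15)
})

test_that("intact embryos are more elongated than severed at matched cell count", {
  lw <- vapply(1:20, function(seed) {
    gi <- simulate_division_growth("intact", n_target_cells = 100,
                                   seed = seed)
    gs <- simulate_division_growth("severed", n_target_cells = 100,
                                   seed = 10000L + seed)
    c(intact = blade_metrics(gi$snapshots[["100"]])$lw_ratio,
      severed = blade_metrics(gs$snapshots[["100"]])$lw_ratio)
  }, numeric(2))
  dominance <- mean(lw["intact", ] > lw["severed", ])
  expect_gte(dominance, 0.9)
})

test_that("intact embryos have more 3-neighbour (peripheral) cells than severed", {
  prop3 <- function(sim) {
    d <- neighbour_count_distribution(
      neighbour_graph(sim$snapshots[[1]]))
    unname(attr(d, "proportions")["3"])
  }
  p_int <- vapply(1:8, function(s) {
    suppressWarnings(prop3(simulate_division_growth(
      "intact", n_target_cells = 60, seed = s)))
  }, numeric(1))
  p_sev <- vapply(1:8, function(s) {
    suppressWarnings(prop3(simulate_division_growth(
      "severed", n_target_cells = 60, seed = 20000L + s)))
  }, numeric(1))
  expect_gt(mean(p_int), mean(p_sev))
})

test_that("parametric growth series are reproducible and respect noise settings", {
  s1 <- generate_growth_series(26, 120, 2, noise_cv = 0.1, seed = 12)
  s2 <- generate_growth_series(26, 120, 2, noise_cv = 0.1, seed = 12)
  expect_identical(s1$n_cells, s2$n_cells)
  s0 <- generate_growth_series(26, 120, 2, noise_cv = 0)
  expect_equal(s0$n_cells, 8 * 2^((s0$time_h - s0$time_h[s0$t0_index]) / 26))
  expect_error(generate_growth_series(doubling_h = 0), "positive")
})

test_that("generator RNG use does not disturb the caller's RNG stream", {
  set.seed(314)
  before <- .Random.seed
  invisible(generate_lamina(4, 4, jitter = 0.2, seed = 7))
  invisible(simulate_division_growth("intact", n_target_cells = 10,
                                     seed = 7))
  expect_identical(.Random.seed, before)
})
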
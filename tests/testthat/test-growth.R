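test_that("series validation enforces time order and monotone counts", {
  expect_error(growth_series(c(0, 0, 2), c(1, 2, 3)), "increasing")
  expect_error(growth_series(c(0, 2, 4), c(4, 3, 5)), "non-decreasing")
  expect_error(growth_series(c(0, 2), c(0, 1)), "positive")
  expect_error(growth_series(c(0, 2), c(1, 2), t0_index = 5), "range")
  s <- growth_series(c(0, 24, 48, 72), c(2, 4, 8, 16), t0_index = 3)
  expect_s3_class(s, "growth_series")
})

test_that("alignment shifts the flagged transition to t = 0", {
  s <- growth_series(c(0, 24, 48, 72), c(2, 4, 8, 16), t0_index = 3)
  a <- align_series(s)
  expect_equal(a$time_h, c(-48, -24, 0, 24))
  s1 <- growth_series(c(10, 20, 30), c(2, 4, 8), t0_index = 1)
  expect_equal(align_series(s1)$time_h, c(0, 10, 20))
  noflag <- growth_series(c(0, 24), c(2, 4))
  expect_error(align_series(noflag), "t0")
})

test_that("a noiseless exponential recovers its doubling time to machine precision", {
  for (tau_true in c(12, 26, 50)) {
    s <- generate_growth_series(doubling_h = tau_true, duration_h = 168,
                                step_h = 2, noise_cv = 0)
    f <- fit_growth_rate(s)
    expect_lt(abs(f$doubling_time_h - tau_true) / tau_true, 1e-9)
    expect_equal(f$r, 2^(1 / tau_true), tolerance = 1e-12)
    expect_equal(f$r2, 1, tolerance = 1e-9)
  }
})

test_that("the window is applied inclusively and translation leaves the fit unchanged", {
  s <- generate_growth_series(doubling_h = 26, duration_h = 168, step_h = 2,
                              noise_cv = 0.15, seed = 7)
  f <- fit_growth_rate(s)
  # shifting all times (window follows t0, which shifts too) changes nothing
  s2 <- s
  s2$time_h <- s2$time_h + 1000
  f2 <- fit_growth_rate(s2)
  expect_equal(f2$r, f$r, tolerance = 1e-12)
  expect_equal(f2$doubling_time_h, f$doubling_time_h, tolerance = 1e-12)
  # observations outside [-48, 72] are excluded: truncating the series
  # beyond the window does not change the fit
  aligned <- align_series(s)
  keep <- aligned$time_h >= -48 & aligned$time_h <= 72
  s3 <- growth_series(aligned$time_h[keep], aligned$n_cells[keep],
                      t0_index = which(aligned$time_h[keep] == 0))
  f3 <- fit_growth_rate(s3)
  expect_equal(f3$r, f$r, tolerance = 1e-12)
  expect_equal(f3$n_points, f$n_points)
})

test_that("a constant series yields r = 1 and infinite doubling time with warning", {
  s <- growth_series(seq(0, 48, 4), rep(8, 13), t0_index = 7)
  expect_warning(f <- fit_growth_rate(s), "infinite")
  expect_equal(f$r, 1)
  expect_equal(f$doubling_time_h, Inf)
})

test_that("insufficient or degenerate data errors", {
  s <- growth_series(c(-100, 100, 200), c(1, 2, 4), t0_index = 1)
  expect_error(fit_growth_rate(s), "insufficient")
  short <- generate_growth_series(doubling_h = 26, duration_h = 10,
                                  step_h = 20, noise_cv = 0)
  expect_error(fit_growth_rate(short), "insufficient")
})

test_that("stochastic series recover the doubling time within 15% over 20 seeds", {
  taus <- vapply(1:20, function(seed) {
    s <- generate_growth_series(doubling_h = 26, duration_h = 168,
                                step_h = 2, noise_cv = 0.1, seed = seed)
    fit_growth_rate(s)$doubling_time_h
  }, numeric(1))
  expect_lt(abs(mean(taus) - 26) / 26, 0.15)
})

test_that("estimated doubling time converges with more replicates", {
  # mean absolute bias of the replicate-group mean shrinks ~ 1/sqrt(n);
  # estimate it by splitting a pool of independent fits into disjoint
  # groups of each size
  pool <- vapply(seq_len(960), function(seed) {
    s <- generate_growth_series(doubling_h = 26, duration_h = 168,
                                step_h = 4, noise_cv = 0.2,
                                seed = 1000L + seed)
    fit_growth_rate(s)$doubling_time_h
  }, numeric(1))
  mean_abs_bias <- vapply(c(4, 16, 64), function(n_rep) {
    groups <- split(pool, ceiling(seq_along(pool) / n_rep))
    mean(abs(vapply(groups, mean, numeric(1)) - 26))
  }, numeric(1))
  expect_true(all(diff(mean_abs_bias) < 0))
})

test_that("group summaries average finite doubling times and flag infinities", {
  mk <- function(tau, id) {
    s <- generate_growth_series(doubling_h = tau, duration_h = 168,
                                step_h = 2, noise_cv = 0, embryo_id = id)
    fit_growth_rate(s)
  }
  fits <- list(mk(24, "a"), mk(26, "b"), mk(28, "c"))
  out <- summarise_growth(fits, groups = rep("intact", 3))
  expect_equal(out$mean_tau_h, 26, tolerance = 1e-9)
  expect_equal(out$n, 3L)

  flat <- suppressWarnings(
    fit_growth_rate(growth_series(seq(0, 48, 4), rep(8, 13), t0_index = 7)))
  expect_warning(
    out2 <- summarise_growth(c(fits, list(flat)),
                             groups = c(rep("intact", 3), "intact")),
    "excluded")
  expect_equal(out2$mean_tau_h, 26, tolerance = 1e-9)
  expect_equal(out2$n_finite, 3L)

  two <- summarise_growth(list(mk(26, "x"), mk(26, "y")),
                          groups = c("E0", "E1"))
  expect_equal(two$mean_tau_h[1], two$mean_tau_h[2])
  expect_error(summarise_growth(list(), character(0)), "no fits")
})
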
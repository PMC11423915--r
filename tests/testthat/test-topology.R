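test_that("shared wall length handles full, partial and absent contact", {
  a <- cell_contour(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)), "a")
  b <- cell_contour(cbind(c(1, 2, 2, 1), c(0, 0, 1, 1)), "b")
  # full unit edge shared; the proximity capsule adds at most ~2*tol of the
  # perpendicular walls near each shared corner
  s <- shared_wall_length(a, b, proximity_tol = 0.05)
  expect_gte(s, 1)
  expect_lte(s, 1 + 4 * 0.05)

  far <- cell_contour(cbind(c(6, 7, 7, 6), c(0, 0, 1, 1)), "far")
  expect_equal(shared_wall_length(a, far), 0)

  # offset so the overlapping edge segment is 0.3 um
  c3 <- cell_contour(cbind(c(1, 2, 2, 1), c(0.7, 0.7, 1.7, 1.7)), "c")
  tol <- 0.05
  s3 <- shared_wall_length(a, c3, proximity_tol = tol)
  set.seed(5)
  orc <- oracle_shared_length(a$vertices, c3$vertices, tol, n_samples = 1e5)
  expect_lt(abs(s3 - orc), 0.01)     # matches the dense-sampling oracle
  expect_lt(abs(s3 - 0.3), 3 * tol)  # nominal overlap plus corner effects
})

test_that("shared wall length is symmetric", {
  set.seed(17)
  for (rep in 1:5) {
    g <- generate_lamina(3, 3, cell_size = 4, jitter = 0.25, seed = rep)
    cells <- g$lamina$cells
    s_ab <- shared_wall_length(cells[[1]], cells[[2]])
    s_ba <- shared_wall_length(cells[[2]], cells[[1]])
    expect_lt(abs(s_ab - s_ba), 1e-6)
  }
})

test_that("grid laminae follow the peripheral/internal neighbour law", {
  g <- generate_lamina(3, 3, cell_size = 10)
  ng <- neighbour_graph(g$lamina)
  counts <- neighbour_counts(ng)
  centre <- counts[["r02c02"]]
  expect_equal(centre, 4L)  # above, below, left, right
  corners <- counts[c("r01c01", "r01c03", "r03c01", "r03c03")]
  expect_equal(unname(corners), rep(2L, 4))
  dist <- neighbour_count_distribution(ng)
  expect_equal(unname(dist[c("2", "3", "4")]), c(4L, 4L, 1L))
  expect_equal(sum(dist), 9L)
  expect_equal(sum(attr(dist, "proportions")), 1)

  # 1x8 phase-I-like stack: path graph
  st <- generate_lamina(8, 1, cell_size = 8)
  cst <- neighbour_counts(neighbour_graph(st$lamina))
  expect_equal(sum(cst == 1L), 2L)
  expect_equal(sum(cst == 2L), 6L)

  # r x c law on a larger grid: corners 2, edges 3, interior 4
  g6 <- generate_lamina(6, 6, cell_size = 6)
  c6 <- neighbour_counts(neighbour_graph(g6$lamina))
  expect_equal(sum(c6 == 2L), 4L)
  expect_equal(sum(c6 == 3L), 16L)
  expect_equal(sum(c6 == 4L), 16L)
})

test_that("4x12 grid interior count matches the brute-force oracle", {
  g <- generate_lamina(4, 12, cell_size = 5)
  ng <- neighbour_graph(g$lamina)
  counts <- neighbour_counts(ng)
  expect_equal(sum(counts == 4L), 2L * 10L)
  brute <- oracle_neighbour_edges(g$lamina)
  expect_equal(nrow(ng$edges), nrow(brute))
  key <- function(df) sort(paste(df$cell_a, df$cell_b))
  expect_equal(key(ng$edges), key(brute))
})

test_that("pruned construction equals brute force on jittered laminae", {
  set.seed(29)
  for (rep in 1:6) {
    g <- generate_lamina(sample(2:5, 1), sample(2:5, 1), cell_size = 6,
                         jitter = runif(1, 0, 0.35), seed = rep * 13L)
    ng <- neighbour_graph(g$lamina)
    brute <- oracle_neighbour_edges(g$lamina)
    n_brute <- if (is.null(brute)) 0L else nrow(brute)
    expect_equal(nrow(ng$edges), n_brute)
    if (n_brute > 0) {
      key <- function(df) sort(paste(df$cell_a, df$cell_b))
      expect_equal(key(ng$edges), key(brute))
    }
  }
})

test_that("jittered grids keep the generator's ground-truth adjacency", {
  g <- generate_lamina(4, 4, cell_size = 8, jitter = 0.3, seed = 31)
  ng <- neighbour_graph(g$lamina)
  key <- function(df) {
    sort(apply(cbind(df$cell_a, df$cell_b), 1,
               function(r) paste(sort(r), collapse = "|")))
  }
  # ground-truth walls are all >> 0.2 um at this cell size
  expect_true(all(g$truth$adjacency$shared_um > 0.2))
  expect_equal(key(ng$edges), key(g$truth$adjacency))
  # measured shared lengths approximate the true single-segment walls
  m <- merge(ng$edges, g$truth$adjacency,
             by = c("cell_a", "cell_b"), suffixes = c("", "_true"))
  expect_true(all(abs(m$shared_um - m$shared_um_true) < 0.25))
})

test_that("raising min_shared never adds edges", {
  g <- generate_lamina(4, 4, cell_size = 2, jitter = 0.2, seed = 3)
  thresholds <- c(0.2, 0.5, 1, 1.8)
  n_edges <- vapply(thresholds, function(ms) {
    nrow(neighbour_graph(g$lamina, min_shared = ms)$edges)
  }, integer(1))
  expect_true(all(diff(n_edges) <= 0))
})

test_that("degenerate and empty inputs error cleanly", {
  g <- generate_lamina(2, 2, cell_size = 5)
  ng <- neighbour_graph(g$lamina)
  expect_error(neighbour_graph(g$lamina, min_shared = 0), "positive")
  expect_error(shared_wall_length(g$lamina$cells[[1]],
                                  g$lamina$cells[[2]],
                                  proximity_tol = -1), "positive")
  empty <- structure(list(cell_ids = character(0),
                          edges = data.frame(),
                          min_shared = 0.2, proximity_tol = 0.05),
                     class = "neighbour_graph")
  expect_error(neighbour_count_distribution(empty), "empty")
})
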
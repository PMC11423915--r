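# Independent oracles used to check the geometry and statistics code.
# Deliberately naive implementations (Monte Carlo, brute force, exhaustive
# enumeration) that share no code with the package internals.

# Vectorised even-odd point-in-polygon (independent re-derivation).
oracle_in_polygon <- function(px, py, v) {
  n <- nrow(v)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- v[i, 1]; yi <- v[i, 2]
    xj <- v[j, 1]; yj <- v[j, 2]
    hit <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, hit)
    j <- i
  }
  inside
}

# Monte Carlo area of one polygon by rejection sampling in its bbox.
# Returns estimate and standard error.
oracle_mc_area <- function(v, n_samples = 1e6) {
  x0 <- min(v[, 1]); x1 <- max(v[, 1])
  y0 <- min(v[, 2]); y1 <- max(v[, 2])
  px <- runif(n_samples, x0, x1)
  py <- runif(n_samples, y0, y1)
  p <- mean(oracle_in_polygon(px, py, v))
  box <- (x1 - x0) * (y1 - y0)
  list(estimate = p * box,
       se = sqrt(p * (1 - p) / n_samples) * box)
}

# Monte Carlo area of the intersection of two polygons.
oracle_mc_intersection <- function(va, vb, n_samples = 1e6) {
  x0 <- min(va[, 1], vb[, 1]); x1 <- max(va[, 1], vb[, 1])
  y0 <- min(va[, 2], vb[, 2]); y1 <- max(va[, 2], vb[, 2])
  px <- runif(n_samples, x0, x1)
  py <- runif(n_samples, y0, y1)
  p <- mean(oracle_in_polygon(px, py, va) & oracle_in_polygon(px, py, vb))
  box <- (x1 - x0) * (y1 - y0)
  list(estimate = p * box,
       se = sqrt(p * (1 - p) / n_samples) * box)
}

# Monte Carlo area of the union of a list of polygons.
oracle_mc_union_area <- function(polys, n_samples = 1e6) {
  allv <- do.call(rbind, polys)
  x0 <- min(allv[, 1]); x1 <- max(allv[, 1])
  y0 <- min(allv[, 2]); y1 <- max(allv[, 2])
  px <- runif(n_samples, x0, x1)
  py <- runif(n_samples, y0, y1)
  inside <- rep(FALSE, n_samples)
  for (v in polys) inside <- inside | oracle_in_polygon(px, py, v)
  p <- mean(inside)
  box <- (x1 - x0) * (y1 - y0)
  list(estimate = p * box,
       se = sqrt(p * (1 - p) / n_samples) * box)
}

# Brute-force convex hull by the O(n^3) half-plane test: a point pair is a
# hull edge iff every other point lies on one side.
oracle_hull_indices <- function(pts) {
  n <- nrow(pts)
  on_hull <- rep(FALSE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      cross <- (pts[j, 1] - pts[i, 1]) * (pts[, 2] - pts[i, 2]) -
        (pts[j, 2] - pts[i, 2]) * (pts[, 1] - pts[i, 1])
      if (all(cross[-c(i, j)] <= 1e-12)) {
        on_hull[i] <- TRUE
        on_hull[j] <- TRUE
      }
    }
  }
  which(on_hull)
}

# Minimal enclosing rectangle area by a dense sweep over orientations.
# The area profile has a kink at the optimum, so after the 1e5-step grid a
# local refinement pass around the best coarse angle removes the O(step)
# discretisation error.
oracle_mbr_sweep_area <- function(v, n_angles = 1e5) {
  sweep_once <- function(angles) {
    ca <- cos(angles); sa <- sin(angles)
    min_u <- rep(Inf, length(angles)); max_u <- -min_u
    min_w <- min_u; max_w <- -min_u
    for (k in seq_len(nrow(v))) {
      pu <- ca * v[k, 1] + sa * v[k, 2]
      pw <- -sa * v[k, 1] + ca * v[k, 2]
      min_u <- pmin(min_u, pu); max_u <- pmax(max_u, pu)
      min_w <- pmin(min_w, pw); max_w <- pmax(max_w, pw)
    }
    (max_u - min_u) * (max_w - min_w)
  }
  step <- pi / n_angles
  coarse <- seq(0, pi - step, by = step)
  a_coarse <- sweep_once(coarse)
  best <- coarse[which.min(a_coarse)]
  fine <- seq(best - step, best + step, length.out = 2001)
  min(min(a_coarse), min(sweep_once(fine)))
}

# Dense boundary sampling measure of shared wall length: fraction of
# sample points on a's boundary within tol of b's boundary, times |a|.
oracle_shared_length <- function(va, vb, tol, n_samples = 1e5) {
  sample_boundary <- function(v, n) {
    e_from <- v
    e_to <- rbind(v[-1, , drop = FALSE], v[1, , drop = FALSE])
    len <- sqrt(rowSums((e_to - e_from)^2))
    cum <- cumsum(len)
    s <- seq(0, cum[length(cum)], length.out = n + 1)[-(n + 1)]
    idx <- findInterval(s, c(0, cum[-length(cum)]))
    t <- (s - c(0, cum)[idx]) / len[idx]
    e_from[idx, , drop = FALSE] + t * (e_to[idx, , drop = FALSE] -
                                         e_from[idx, , drop = FALSE])
  }
  dist_to_boundary <- function(p, v) {
    e_from <- v
    e_to <- rbind(v[-1, , drop = FALSE], v[1, , drop = FALSE])
    d <- rep(Inf, nrow(p))
    for (j in seq_len(nrow(v))) {
      q0 <- e_from[j, ]; q1 <- e_to[j, ]
      e <- q1 - q0
      L2 <- sum(e^2)
      t <- pmin(1, pmax(0, ((p[, 1] - q0[1]) * e[1] +
                              (p[, 2] - q0[2]) * e[2]) / L2))
      dj <- sqrt((p[, 1] - q0[1] - t * e[1])^2 +
                   (p[, 2] - q0[2] - t * e[2])^2)
      d <- pmin(d, dj)
    }
    d
  }
  directed <- function(va, vb) {
    pts <- sample_boundary(va, n_samples)
    per <- sum(sqrt(rowSums((rbind(va[-1, , drop = FALSE],
                                   va[1, , drop = FALSE]) - va)^2)))
    mean(dist_to_boundary(pts, vb) <= tol) * per
  }
  (directed(va, vb) + directed(vb, va)) / 2
}

# Brute-force neighbour graph: all pairs, no bounding-box pruning.
oracle_neighbour_edges <- function(lam, min_shared = 0.2,
                                   proximity_tol = 0.05) {
  ids <- vapply(lam$cells, function(c) c$cell_id, character(1))
  nc <- length(ids)
  out <- list()
  for (i in seq_len(nc - 1)) {
    for (j in (i + 1):nc) {
      s <- shared_wall_length(lam$cells[[i]], lam$cells[[j]], proximity_tol)
      if (s >= min_shared) {
        out[[length(out) + 1]] <- data.frame(cell_a = ids[i],
                                             cell_b = ids[j],
                                             shared_um = s)
      }
    }
  }
  if (length(out) == 0) return(NULL)
  do.call(rbind, out)
}

# Welch statistic, df and two-tailed p re-derived from the formulas.
oracle_welch <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t_stat <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  p <- 2 * pt(-abs(t_stat), df)
  list(statistic = t_stat, df = df, p_value = p)
}

# Exact two-tailed Mann-Whitney p-value by exhaustive enumeration of all
# C(n_a + n_b, n_a) assignments of ranks to group a (no ties assumed).
oracle_mw_exact <- function(a, b) {
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combos <- combn(na + nb, na)
  u_all <- apply(combos, 2, function(ix) sum(ix) - na * (na + 1) / 2)
  # two-tailed: double the smaller tail, capped at 1
  p_low <- mean(u_all <= u_obs)
  p_high <- mean(u_all >= u_obs)
  min(1, 2 * min(p_low, p_high))
}

# Pearson chi-square by the direct sum over cells.
oracle_chi2 <- function(m) {
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  stat <- sum((m - expected)^2 / expected)
  df <- (nrow(m) - 1) * (ncol(m) - 1)
  list(statistic = stat, df = df, p_value = pchisq(stat, df,
                                                   lower.tail = FALSE))
}

# Exhaustive binomial composition over all 2^n outcome vectors.
oracle_binomial_enum <- function(p, n) {
  outcomes <- expand.grid(rep(list(c(0, 1)), n))
  w <- apply(outcomes, 1, function(o) prod(ifelse(o == 1, p, 1 - p)))
  k <- rowSums(outcomes)
  list(p_all_normal = sum(w[k == 0]), expected_abnormal = sum(w * k))
}

# Random simple (star-shaped) polygon around the origin.
random_star_polygon <- function(n = 12, r_min = 1, r_max = 3) {
  ang <- sort(runif(n, 0, 2 * pi))
  r <- runif(n, r_min, r_max)
  cbind(r * cos(ang), r * sin(ang))
}

# Random convex polygon: convex hull of random points.
random_convex_polygon <- function(n_points = 12) {
  pts <- matrix(runif(2 * n_points, -2, 2), ncol = 2)
  idx <- grDevices::chull(pts)
  pts[idx, , drop = FALSE]
}

rot2 <- function(v, theta) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  v %*% t(R)
}

translate2 <- function(v, dx, dy) cbind(v[, 1] + dx, v[, 2] + dy)
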
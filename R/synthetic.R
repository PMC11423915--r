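# Synthetic laminae and division simulations with known ground truth.
#
# Real embryo laminae are monolayers of quadrilateral-ish cells arranged in
# rows and columns; blades elongate along the apico-basal axis (l/w from ~1
# to ~3.5) and cell number grows exponentially with a ~26 h doubling.  The
# generators emulate exactly these features: a (jittered) rectangular grid
# tessellation for static geometry, and an event-driven division simulator
# in which transverse divisions extend the apico-basal axis and
# longitudinal divisions, once permitted, extend the medio-lateral axis.
# Every generator returns the analytic ground truth of its construction so
# analysis code can be tested against values it did not compute.

# Run code with a locally-set RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Generate a grid-tessellation lamina with ground truth
#'
#' Builds a rows x cols monolayer of quadrilateral cells.  Vertices are
#' shared between adjacent cells, so the tessellation is a partition of the
#' blade (duplicated walls coincide exactly).  \code{jitter} displaces every
#' grid vertex once by a uniform fraction of the cell size in each
#' coordinate, degrading rectangularity without breaking the partition;
#' \code{elongation_target} applies an area-preserving anisotropic stretch
#' so the blade length/width ratio equals the target while each cell keeps
#' mean area \code{cell_size^2}; \code{mask = "ellipse"}
#' keeps only cells whose centre falls inside the ellipse inscribed in the
#' grid's bounding box, emulating a rounded blade outline.
#'
#' @param rows,cols grid dimensions (>= 1).
#' @param cell_size target cell side in um.
#' @param jitter vertex displacement as a fraction of cell size, in
#'   [0, 0.5); 0 gives exact rectangles.
#' @param elongation_target desired blade l/w ratio (>= 1), or \code{NULL}
#'   to keep square cells.
#' @param mask \code{"none"} or \code{"ellipse"}.
#' @param seed integer seed for reproducible jitter, or \code{NULL}.
#' @param embryo_id,stage_group metadata for the generated lamina.
#' @return List with elements \code{lamina} (a \code{\link{lamina}}),
#'   \code{truth} (analytic per-cell morphometrics, grid adjacency with
#'   wall lengths, and blade-level area/axes computed from the
#'   construction, not from the analysis code) and \code{spec} (the
#'   generating parameters).
#' @examples
#' g <- generate_lamina(rows = 6, cols = 6, cell_size = 8, jitter = 0.2,
#'                      seed = 1)
#' g$truth$blade$area_um2
#' @export
generate_lamina <- function(rows, cols, cell_size = 8, jitter = 0,
                            elongation_target = NULL,
                            mask = c("none", "ellipse"), seed = NULL,
                            embryo_id = "synthetic",
                            stage_group = "intact") {
  mask <- match.arg(mask)
  if (rows < 1L || cols < 1L || rows != round(rows) || cols != round(cols)) {
    stop("`rows` and `cols` must be positive integers", call. = FALSE)
  }
  if (cell_size <= 0) stop("`cell_size` must be positive", call. = FALSE)
  if (jitter < 0 || jitter >= 0.5) {
    stop("`jitter` must be in [0, 0.5)", call. = FALSE)
  }
  dx <- cell_size
  dy <- cell_size
  if (!is.null(elongation_target)) {
    if (elongation_target < 1) {
      stop("`elongation_target` must be >= 1", call. = FALSE)
    }
    # area-preserving anisotropic stretch so blade l/w hits the target
    # while each cell keeps area cell_size^2
    if (rows >= cols) {
      f <- elongation_target * cols / rows
      dy <- cell_size * sqrt(f); dx <- cell_size / sqrt(f)
    } else {
      f <- elongation_target * rows / cols
      dx <- cell_size * sqrt(f); dy <- cell_size / sqrt(f)
    }
  }
  rows <- as.integer(rows); cols <- as.integer(cols)
  # shared vertex field: (rows+1) x (cols+1), y up, x right
  vx <- outer(rep(1, rows + 1L), (0:cols) * dx)
  vy <- outer((0:rows) * dy, rep(1, cols + 1L))
  if (jitter > 0) {
    .with_seed(seed, {
      amp <- jitter * min(dx, dy)
      vx <- vx + matrix(stats::runif((rows + 1L) * (cols + 1L), -amp, amp),
                        rows + 1L)
      vy <- vy + matrix(stats::runif((rows + 1L) * (cols + 1L), -amp, amp),
                        rows + 1L)
    })
  }
  keep <- matrix(TRUE, rows, cols)
  if (mask == "ellipse") {
    cx0 <- cols * dx / 2; cy0 <- rows * dy / 2
    a <- cols * dx / 2; b <- rows * dy / 2
    for (i in seq_len(rows)) for (j in seq_len(cols)) {
      ccx <- (j - 0.5) * dx; ccy <- (i - 0.5) * dy
      keep[i, j] <- ((ccx - cx0) / a)^2 + ((ccy - cy0) / b)^2 <= 1
    }
    if (!any(keep)) stop("ellipse mask removed every cell", call. = FALSE)
  }
  cells <- list()
  truth_rows <- list()
  idx <- matrix(NA_integer_, rows, cols)
  k <- 0L
  quad_area <- function(q) {
    # shoelace, inlined at construction time
    x <- q[, 1L]; y <- q[, 2L]
    abs(sum(x * c(y[-1L], y[1L]) - c(x[-1L], x[1L]) * y)) / 2
  }
  for (i in seq_len(rows)) for (j in seq_len(cols)) {
    if (!keep[i, j]) next
    k <- k + 1L
    idx[i, j] <- k
    q <- rbind(c(vx[i, j], vy[i, j]),
               c(vx[i, j + 1L], vy[i, j + 1L]),
               c(vx[i + 1L, j + 1L], vy[i + 1L, j + 1L]),
               c(vx[i + 1L, j], vy[i + 1L, j]))
    cid <- sprintf("r%02dc%02d", i, j)
    cells[[k]] <- cell_contour(q, cid)
    per <- sum(sqrt(rowSums((q[c(2L, 3L, 4L, 1L), ] - q)^2)))
    truth_rows[[k]] <- data.frame(
      cell_id = cid, row = i, col = j,
      area_um2 = quad_area(q),
      perimeter_um = per,
      elongation = if (jitter == 0) max(dx, dy) / min(dx, dy) else NA_real_,
      rectangularity = if (jitter == 0) 1 else NA_real_,
      stringsAsFactors = FALSE)
  }
  truth_cells <- do.call(rbind, truth_rows)
  # grid adjacency among kept cells; each shared wall is one segment
  adj <- list()
  for (i in seq_len(rows)) for (j in seq_len(cols)) {
    if (is.na(idx[i, j])) next
    if (j < cols && !is.na(idx[i, j + 1L])) {  # vertical wall to the right
      w <- sqrt((vx[i, j + 1L] - vx[i + 1L, j + 1L])^2 +
                  (vy[i, j + 1L] - vy[i + 1L, j + 1L])^2)
      adj[[length(adj) + 1L]] <- data.frame(
        cell_a = sprintf("r%02dc%02d", i, j),
        cell_b = sprintf("r%02dc%02d", i, j + 1L),
        shared_um = w, stringsAsFactors = FALSE)
    }
    if (i < rows && !is.na(idx[i + 1L, j])) {  # horizontal wall above
      w <- sqrt((vx[i + 1L, j] - vx[i + 1L, j + 1L])^2 +
                  (vy[i + 1L, j] - vy[i + 1L, j + 1L])^2)
      adj[[length(adj) + 1L]] <- data.frame(
        cell_a = sprintf("r%02dc%02d", i, j),
        cell_b = sprintf("r%02dc%02d", i + 1L, j),
        shared_um = w, stringsAsFactors = FALSE)
    }
  }
  truth_adj <- if (length(adj) > 0L) do.call(rbind, adj) else
    data.frame(cell_a = character(0), cell_b = character(0),
               shared_um = numeric(0))
  ext_x <- cols * dx; ext_y <- rows * dy
  truth_blade <- list(
    area_um2 = sum(truth_cells$area_um2),  # partition: union = sum
    main_axis_length = if (jitter == 0 && mask == "none")
      max(ext_x, ext_y) else NA_real_,
    secondary_axis_length = if (jitter == 0 && mask == "none")
      min(ext_x, ext_y) else NA_real_,
    lw_ratio = if (jitter == 0 && mask == "none")
      max(ext_x, ext_y) / min(ext_x, ext_y) else NA_real_,
    main_axis_angle = if (jitter == 0 && mask == "none") {
      if (ext_x >= ext_y) 0 else pi / 2
    } else NA_real_)
  list(lamina = lamina(cells, embryo_id = embryo_id,
                       stage_group = stage_group),
       truth = list(cells = truth_cells, adjacency = truth_adj,
                    blade = truth_blade),
       spec = list(rows = rows, cols = cols, cell_size = cell_size,
                   dx = dx, dy = dy, jitter = jitter,
                   elongation_target = elongation_target, mask = mask,
                   seed = seed))
}

#' Simulate embryo growth by cell division
#'
#' Event-driven simulation of the early embryo's division programme.  Cells
#' live on an integer lattice (apico-basal position x lateral position);
#' per-cell cycle times are gamma distributed (mean \code{mean_cycle_h},
#' coefficient of variation \code{cycle_cv}).  The first division is always
#' transverse.  Longitudinal divisions are forbidden until the embryo
#' reaches \code{longitudinal_onset} cells (default 8 when attached to the
#' maternal stalk, 2 when severed — the repression that the maternal signal
#' exerts); once permitted, each division is longitudinal with probability
#' \code{p_longitudinal}.  The default probability is also mode-dependent
#' (intact 0.3, severed 0.5): in attached embryos the maternal repression
#' persists as a transverse bias through phase II, which is what keeps
#' intact blades elongated while severed blades grow round.  A transverse division inserts a new lattice line
#' along the apico-basal axis (shifting distal cells), a longitudinal one
#' along the medio-lateral axis, so intact embryos first build a 1 x n
#' stack and severed embryos widen early.
#'
#' @param mode \code{"intact"} or \code{"severed"}.
#' @param n_target_cells stop once the embryo reaches this many cells.
#' @param mean_cycle_h mean cell-cycle time in hours (default 26).
#' @param cycle_cv coefficient of variation of cycle times (default 0.25;
#'   0 gives synchronous, deterministic cycles).
#' @param longitudinal_onset cell count from which longitudinal divisions
#'   are permitted; \code{NULL} picks the mode default (intact 8,
#'   severed 2).
#' @param p_longitudinal probability that a permitted division is
#'   longitudinal; \code{NULL} picks the mode default (intact 0.3,
#'   severed 0.5).
#' @param cell_size rendered cell side in um.
#' @param step_h observation interval of the emitted growth series (hours).
#' @param snapshot_counts cell counts at which to render lamina snapshots
#'   (default: final count only).
#' @param seed integer seed, or \code{NULL}.
#' @return List with \code{snapshots} (named list of \code{\link{lamina}}),
#'   \code{series} (a \code{\link{growth_series}} with \code{t0_index} at
#'   the first observation after the first longitudinal division),
#'   \code{events} (data frame: time_h, orientation, n_cells_after),
#'   \code{t0_h} (time of the first longitudinal division, or NA) and
#'   \code{mode}.
#' @examples
#' sim <- simulate_division_growth("intact", n_target_cells = 8, seed = 1)
#' table(sim$events$orientation)  # all transverse before the 8-cell stage
#' @export
simulate_division_growth <- function(mode = c("intact", "severed"),
                                     n_target_cells = 100,
                                     mean_cycle_h = 26, cycle_cv = 0.25,
                                     longitudinal_onset = NULL,
                                     p_longitudinal = NULL,
                                     cell_size = 8, step_h = 2,
                                     snapshot_counts = NULL, seed = NULL) {
  mode <- match.arg(mode)
  if (n_target_cells < 2L) {
    stop("`n_target_cells` must be at least 2", call. = FALSE)
  }
  if (mean_cycle_h <= 0) stop("`mean_cycle_h` must be positive",
                              call. = FALSE)
  if (cycle_cv < 0) stop("`cycle_cv` must be non-negative", call. = FALSE)
  if (is.null(longitudinal_onset)) {
    longitudinal_onset <- if (mode == "intact") 8L else 2L
  }
  if (is.null(p_longitudinal)) {
    p_longitudinal <- if (mode == "intact") 0.3 else 0.5
  }
  if (is.null(snapshot_counts)) snapshot_counts <- n_target_cells
  .with_seed(seed, {
    draw_cycle <- function(n) {
      if (cycle_cv < 1e-8) rep(mean_cycle_h, n)
      else stats::rgamma(n, shape = 1 / cycle_cv^2,
                         scale = mean_cycle_h * cycle_cv^2)
    }
    st <- data.frame(i = 1L, j = 1L, next_div = draw_cycle(1L))
    events <- list()
    snapshots <- list()
    t0_h <- NA_real_
    render <- function(st, count) {
      # compact the lattice into a hole-free monolayer: drop empty
      # apico-basal tiers, then stack each tier's cells contiguously,
      # centred on the midline (tissue closes ranks around the gaps the
      # insertion bookkeeping leaves behind)
      tier_x <- match(st$i, sort(unique(st$i)))
      cells <- vector("list", nrow(st))
      k <- 0L
      for (tx in sort(unique(tier_x))) {
        members <- which(tier_x == tx)
        members <- members[order(st$j[members])]
        n_t <- length(members)
        y_base <- -n_t * cell_size / 2
        for (m in seq_along(members)) {
          k <- k + 1L
          x0 <- (tx - 1L) * cell_size
          y0 <- y_base + (m - 1L) * cell_size
          cells[[k]] <- cell_contour(
            rbind(c(x0, y0), c(x0 + cell_size, y0),
                  c(x0 + cell_size, y0 + cell_size),
                  c(x0, y0 + cell_size)),
            sprintf("t%03dn%03d", tx, m))
        }
      }
      lamina(cells, embryo_id = sprintf("%s_n%d", mode, count),
             stage_group = if (mode == "intact") "intact" else "E0")
    }
    while (nrow(st) < n_target_cells) {
      k <- which.min(st$next_div)
      t <- st$next_div[k]
      n_now <- nrow(st)
      longitudinal <- n_now > 1L && n_now >= longitudinal_onset &&
        stats::runif(1L) < p_longitudinal
      i0 <- st$i[k]; j0 <- st$j[k]
      occupied <- function(ii, jj) any(st$i == ii & st$j == jj)
      if (longitudinal) {
        # reuse a free flanking slot if one exists, else insert a lattice
        # line (shifting cells beyond it); reuse keeps the tissue compact
        if (!occupied(i0, j0 + 1L)) {
          jd <- j0 + 1L
        } else if (!occupied(i0, j0 - 1L)) {
          jd <- j0 - 1L
        } else {
          st$j[st$j > j0] <- st$j[st$j > j0] + 1L
          jd <- j0 + 1L
        }
        daughters <- data.frame(i = c(i0, i0), j = c(j0, jd),
                                next_div = t + draw_cycle(2L))
        if (is.na(t0_h)) t0_h <- t
      } else {
        if (!occupied(i0 + 1L, j0)) {
          id <- i0 + 1L
        } else if (!occupied(i0 - 1L, j0)) {
          id <- i0 - 1L
        } else {
          st$i[st$i > i0] <- st$i[st$i > i0] + 1L
          id <- i0 + 1L
        }
        daughters <- data.frame(i = c(i0, id), j = c(j0, j0),
                                next_div = t + draw_cycle(2L))
      }
      st <- rbind(st[-k, , drop = FALSE], daughters)
      events[[length(events) + 1L]] <- data.frame(
        time_h = t,
        orientation = if (longitudinal) "longitudinal" else "transverse",
        n_cells_after = nrow(st), stringsAsFactors = FALSE)
      if (nrow(st) %in% snapshot_counts) {
        snapshots[[as.character(nrow(st))]] <- render(st, nrow(st))
      }
    }
    events <- do.call(rbind, events)
    t_end <- max(events$time_h)
    obs_t <- seq(0, ceiling(t_end / step_h) * step_h, by = step_h)
    obs_n <- vapply(obs_t, function(tt) 1L + sum(events$time_h <= tt),
                    integer(1L))
    t0_index <- if (is.na(t0_h)) NA_integer_ else
      which(obs_t >= t0_h)[1L]
    series <- growth_series(obs_t, obs_n, t0_index = t0_index,
                            embryo_id = sprintf("%s_sim", mode))
    list(snapshots = snapshots, series = series, events = events,
         t0_h = t0_h, mode = mode,
         longitudinal_onset = longitudinal_onset)
  })
}

#' Generate a parametric growth series
#'
#' Expected cell counts under exponential growth
#' N(t) = n0 * 2^((t - t0) / doubling_h), observed every \code{step_h}
#' hours, with optional multiplicative log-normal noise of coefficient of
#' variation \code{noise_cv} (a running maximum then restores
#' monotonicity, since cells cannot merge).  With \code{noise_cv = 0} the
#' series is exactly exponential and \code{\link{fit_growth_rate}} recovers
#' the doubling time to machine precision.
#'
#' @param doubling_h true doubling time in hours (> 0).
#' @param duration_h total observation span in hours.
#' @param step_h observation interval in hours.
#' @param noise_cv multiplicative noise CV (>= 0).
#' @param n0 expected count at the transition observation.
#' @param t0_frac position of the flagged transition within the series, as
#'   a fraction of \code{duration_h}.
#' @param seed integer seed, or \code{NULL}.
#' @param embryo_id identifier.
#' @return A \code{\link{growth_series}} (counts are expected values, so
#'   real-valued).
#' @export
generate_growth_series <- function(doubling_h = 26, duration_h = 168,
                                   step_h = 2, noise_cv = 0, n0 = 8,
                                   t0_frac = 0.4, seed = NULL,
                                   embryo_id = "synthetic") {
  if (doubling_h <= 0) stop("`doubling_h` must be positive", call. = FALSE)
  if (step_h <= 0 || duration_h <= 0) {
    stop("`step_h` and `duration_h` must be positive", call. = FALSE)
  }
  if (noise_cv < 0) stop("`noise_cv` must be non-negative", call. = FALSE)
  times <- seq(0, duration_h, by = step_h)
  t0_index <- which.min(abs(times - t0_frac * duration_h))
  n <- n0 * 2^((times - times[t0_index]) / doubling_h)
  if (noise_cv > 0) {
    .with_seed(seed, {
      sdlog <- sqrt(log(1 + noise_cv^2))
      n <- n * stats::rlnorm(length(n), meanlog = -sdlog^2 / 2,
                             sdlog = sdlog)
      n <- cummax(n)
    })
  }
  growth_series(times, n, t0_index = t0_index, embryo_id = embryo_id)
}
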
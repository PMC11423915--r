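# Cell-division (growth) rate from time-lapse cell counts.
#
# For each embryo, the clock is set to t = 0 at the phase I -> phase II
# transition (the first longitudinal division).  The count model is
# N(t) = N0 * r^t; ordinary least squares on log N(t) against t over the
# window -48 h <= t <= 72 h gives log(r) as the slope, and the doubling
# time is tau = 1 / log2(r).

#' Growth series
#'
#' Time-stamped cell counts for one embryo, with the index of the
#' observation marking the phase I -> II transition (first longitudinal
#' division).
#'
#' @param time_h numeric vector of observation times (hours), strictly
#'   increasing.
#' @param n_cells positive cell counts, non-decreasing (cells do not merge).
#' @param t0_index index of the first observation at/after the first
#'   longitudinal division, or \code{NA} if unknown.
#' @param embryo_id identifier.
#' @return An object of class \code{growth_series}.
#' @export
growth_series <- function(time_h, n_cells, t0_index = NA_integer_,
                          embryo_id = "embryo") {
  time_h <- as.numeric(time_h)
  n_cells <- as.numeric(n_cells)
  if (length(time_h) != length(n_cells)) {
    stop("`time_h` and `n_cells` must have the same length", call. = FALSE)
  }
  if (length(time_h) < 1L || anyNA(time_h) || anyNA(n_cells)) {
    stop("times and counts must be non-missing", call. = FALSE)
  }
  if (any(diff(time_h) <= 0)) {
    stop("observation times must be strictly increasing", call. = FALSE)
  }
  if (any(n_cells <= 0)) stop("cell counts must be positive", call. = FALSE)
  if (any(diff(n_cells) < 0)) {
    stop("cell counts must be non-decreasing (cells do not merge)",
         call. = FALSE)
  }
  if (!is.na(t0_index) &&
      (t0_index < 1L || t0_index > length(time_h))) {
    stop("`t0_index` out of range", call. = FALSE)
  }
  structure(list(embryo_id = as.character(embryo_id),
                 time_h = time_h, n_cells = n_cells,
                 t0_index = as.integer(t0_index)),
            class = "growth_series")
}

#' @export
print.growth_series <- function(x, ...) {
  cat("<growth_series>", x$embryo_id, "-", length(x$time_h), "observations,",
      if (is.na(x$t0_index)) "t0 not set" else
        paste0("t0 at index ", x$t0_index), "\n")
  invisible(x)
}

#' Align a growth series on the phase I -> II transition
#'
#' Shifts all times so the flagged transition observation sits at t = 0.
#'
#' @param series a \code{\link{growth_series}} with \code{t0_index} set.
#' @return The aligned \code{growth_series}.
#' @export
align_series <- function(series) {
  stopifnot(inherits(series, "growth_series"))
  if (is.na(series$t0_index)) {
    stop("cannot align: no phase I -> II transition (t0) flagged",
         call. = FALSE)
  }
  series$time_h <- series$time_h - series$time_h[series$t0_index]
  series
}

#' Fit the cell-division rate of one embryo
#'
#' Ordinary least squares of log cell number on time over a window around
#' the phase I -> II transition (default -48 h to +72 h, endpoints
#' included).  The multiplicative rate is r = exp(slope) per hour and the
#' doubling time tau = 1 / log2(r) hours.  A non-growing series (slope <= 0)
#' yields r <= 1 and an infinite doubling time, with a warning.
#'
#' @param series a \code{\link{growth_series}}; aligned internally when its
#'   \code{t0_index} is set and its transition time is nonzero.
#' @param window numeric length-2 fitting window in hours around t0.
#' @return An object of class \code{growth_fit}: list with \code{r},
#'   \code{log_N0}, \code{doubling_time_h}, \code{r2}, \code{n_points},
#'   \code{window}, \code{embryo_id}.
#' @examples
#' s <- generate_growth_series(doubling_h = 26, duration_h = 120,
#'                             step_h = 2, noise_cv = 0)
#' fit_growth_rate(s)$doubling_time_h
#' @export
fit_growth_rate <- function(series, window = c(-48, 72)) {
  stopifnot(inherits(series, "growth_series"))
  if (length(window) != 2L || window[1L] >= window[2L]) {
    stop("`window` must be increasing length-2", call. = FALSE)
  }
  if (!is.na(series$t0_index)) series <- align_series(series)
  keep <- series$time_h >= window[1L] & series$time_h <= window[2L]
  t <- series$time_h[keep]
  n <- series$n_cells[keep]
  if (length(t) < 3L) {
    stop("insufficient data: fewer than 3 observations in the fitting window",
         call. = FALSE)
  }
  if (diff(range(t)) < 1e-12) {
    stop("zero variance in observation times", call. = FALSE)
  }
  fit <- stats::lm(log(n) ~ t)
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  r <- exp(slope)
  if (slope > 1e-12) {  # below ~1e-12/h the slope is numerical noise
    tau <- log(2) / slope  # = 1 / log2(r)
  } else {
    warning("non-increasing cell counts: doubling time is infinite",
            call. = FALSE)
    tau <- Inf
  }
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(embryo_id = series$embryo_id,
                 r = r, log_N0 = intercept,
                 doubling_time_h = tau, r2 = r2,
                 n_points = length(t), window = window),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("<growth_fit> %s: r = %.5f / h, tau = %.2f h (R^2 = %.3f, n = %d)\n",
              x$embryo_id, x$r, x$doubling_time_h, x$r2, x$n_points))
  invisible(x)
}

#' Summarise doubling times by stage group
#'
#' Per-group mean and dispersion of the fitted doubling times.  Infinite
#' doubling times (non-growing embryos) are excluded from the means with a
#' warning reporting how many were dropped.
#'
#' @param fits list of \code{growth_fit} objects.
#' @param groups character vector of stage-group labels, one per fit.
#' @return Data frame with one row per group: \code{n}, \code{n_finite},
#'   \code{mean_tau_h}, \code{sd_tau_h}, \code{mean_r}.
#' @export
summarise_growth <- function(fits, groups) {
  if (length(fits) == 0L) stop("no fits supplied", call. = FALSE)
  if (length(groups) != length(fits)) {
    stop("`groups` must have one label per fit", call. = FALSE)
  }
  tau <- vapply(fits, `[[`, numeric(1L), "doubling_time_h")
  r <- vapply(fits, `[[`, numeric(1L), "r")
  n_inf <- sum(!is.finite(tau))
  if (n_inf > 0L) {
    warning(n_inf, " infinite doubling time(s) excluded from group means",
            call. = FALSE)
  }
  out <- do.call(rbind, lapply(split(seq_along(fits), groups), function(ix) {
    ft <- tau[ix][is.finite(tau[ix])]
    if (length(ft) == 0L) {
      stop("group with no finite doubling times", call. = FALSE)
    }
    data.frame(group = groups[ix[1L]],
               n = length(ix),
               n_finite = length(ft),
               mean_tau_h = mean(ft),
               sd_tau_h = if (length(ft) > 1L) stats::sd(ft) else NA_real_,
               mean_r = mean(r[ix][is.finite(tau[ix])]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
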
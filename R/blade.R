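# Blade-level morphometrics.
#
# The blade region is the union of all cell polygons (shared walls are
# duplicated in the tracing, so a plain sum of cell areas would double
# count any sliver of overlap).  Union geometry goes through polyclip;
# orientation of the blade comes from second-order area moments of the
# union region, and blade length/width are the extents of the region
# projected onto the principal directions.

# Union of all cell polygons as a list of rings (x, y); holes are traced
# opposite to outers so signed areas subtract.
.blade_union <- function(lam) {
  polys <- lapply(lam$cells, function(cc) {
    list(x = cc$vertices[, 1L], y = cc$vertices[, 2L])
  })
  acc <- polys[1L]
  if (length(polys) > 1L) {
    for (i in 2L:length(polys)) {
      acc <- polyclip::polyclip(acc, polys[i], op = "union",
                                fillA = "nonzero", fillB = "nonzero")
    }
  }
  acc
}

.ring_matrix <- function(ring) cbind(ring$x, ring$y)

#' Blade surface area
#'
#' Area of the union of all cell polygons, in um^2.  Always at most the sum
#' of per-cell areas, with equality when cells do not overlap (a clean
#' monolayer tessellation).
#'
#' @param lam a \code{\link{lamina}}.
#' @return Blade area in um^2.
#' @export
blade_area <- function(lam) {
  stopifnot(inherits(lam, "lamina"))
  rings <- .blade_union(lam)
  abs(sum(vapply(rings, function(r) .signed_area(.ring_matrix(r)),
                 numeric(1L))))
}

#' Blade principal axes
#'
#' Orientation of the blade from second-order area moments of the union
#' region (principal-axis decomposition of the area covariance); axis
#' lengths are the extents of the blade projected onto the two principal
#' directions, with main >= secondary.
#'
#' @param lam a \code{\link{lamina}}.
#' @return List with \code{main_axis_length}, \code{secondary_axis_length}
#'   (um), and \code{main_axis_angle} (radians in [0, pi)).
#' @export
blade_axes <- function(lam) {
  stopifnot(inherits(lam, "lamina"))
  rings <- .blade_union(lam)
  mom <- lapply(rings, function(r) .ring_moments(.ring_matrix(r)))
  A <- sum(vapply(mom, `[[`, numeric(1L), "area"))
  if (abs(A) < .GEOM_TOL^2) stop("degenerate blade: zero area", call. = FALSE)
  cx <- sum(vapply(mom, `[[`, numeric(1L), "mx")) / A
  cy <- sum(vapply(mom, `[[`, numeric(1L), "my")) / A
  mu_xx <- sum(vapply(mom, `[[`, numeric(1L), "sxx")) - A * cx^2
  mu_yy <- sum(vapply(mom, `[[`, numeric(1L), "syy")) - A * cy^2
  mu_xy <- sum(vapply(mom, `[[`, numeric(1L), "sxy")) - A * cx * cy
  # nearly isotropic second moments leave the orientation undefined (e.g. a
  # square blade); snap to the x axis for determinism
  aniso <- sqrt((2 * mu_xy)^2 + (mu_xx - mu_yy)^2)
  theta <- if (aniso < 1e-6 * (mu_xx + mu_yy)) 0 else
    0.5 * atan2(2 * mu_xy, mu_xx - mu_yy)
  u <- c(cos(theta), sin(theta))
  w <- c(-u[2L], u[1L])
  verts <- do.call(rbind, lapply(lam$cells, function(cc) cc$vertices))
  ext_u <- diff(range(verts %*% u))
  ext_w <- diff(range(verts %*% w))
  if (ext_u >= ext_w) {
    ang <- theta %% pi
    list(main_axis_length = ext_u, secondary_axis_length = ext_w,
         main_axis_angle = ang)
  } else {
    ang <- (theta + pi / 2) %% pi
    list(main_axis_length = ext_w, secondary_axis_length = ext_u,
         main_axis_angle = ang)
  }
}

#' Developmental window from cell count
#'
#' Embryo-size bins in cell counts used to compare stage groups independent
#' of growth delay: [20:47], [48:103], [104:307]; counts outside all bins
#' are labelled "other".
#'
#' @param n integer cell count(s).
#' @return Character vector of window labels.
#' @export
assign_window <- function(n) {
  vapply(as.integer(n), function(k) {
    if (k >= 20L && k <= 47L) "[20:47]"
    else if (k >= 48L && k <= 103L) "[48:103]"
    else if (k >= 104L && k <= 307L) "[104:307]"
    else "other"
  }, character(1L))
}

#' Blade morphometrics record
#'
#' One summary row per embryo: cell count, blade area, principal-axis
#' lengths, length/width ratio and developmental window.
#'
#' @param lam a \code{\link{lamina}}.
#' @return A one-row data frame.
#' @examples
#' g <- generate_lamina(rows = 8, cols = 1, cell_size = 8)
#' blade_metrics(g$lamina)
#' @export
blade_metrics <- function(lam) {
  stopifnot(inherits(lam, "lamina"))
  ax <- blade_axes(lam)
  data.frame(embryo_id = lam$embryo_id,
             stage_group = lam$stage_group,
             n_cells = n_cells(lam),
             window = assign_window(n_cells(lam)),
             blade_area_um2 = blade_area(lam),
             length_um = ax$main_axis_length,
             width_um = ax$secondary_axis_length,
             lw_ratio = ax$main_axis_length / ax$secondary_axis_length,
             main_axis_angle = ax$main_axis_angle,
             stringsAsFactors = FALSE)
}

#' Classify a division-plane orientation
#'
#' A new cell wall is transverse when (nearly) perpendicular to the blade's
#' main (apico-basal) axis, longitudinal when (nearly) parallel to it, and
#' oblique otherwise.  The relative angle is folded into [0, 90] degrees;
#' the oblique band is the set of angles further than \code{oblique_band}
#' degrees from both the parallel and the perpendicular orientation.
#'
#' @param plane_angle direction of the division plane (new wall), radians.
#' @param blade_axis_angle direction of the blade main axis, radians.
#' @param oblique_band half-width of the longitudinal/transverse acceptance
#'   bands, degrees (default 30).
#' @return List with \code{label} ("transverse", "longitudinal" or
#'   "oblique") and \code{plane_angle}, the folded relative angle in
#'   radians in [0, pi/2].
#' @examples
#' classify_division_orientation(pi / 2, 0)$label  # transverse
#' classify_division_orientation(0, 0)$label      # longitudinal
#' @export
classify_division_orientation <- function(plane_angle, blade_axis_angle,
                                          oblique_band = 30) {
  if (!is.finite(plane_angle) || !is.finite(blade_axis_angle)) {
    stop("angles must be finite", call. = FALSE)
  }
  if (oblique_band < 0 || oblique_band > 45) {
    stop("`oblique_band` must be in [0, 45] degrees", call. = FALSE)
  }
  delta <- abs(plane_angle - blade_axis_angle) %% pi
  if (delta > pi / 2) delta <- pi - delta
  deg <- delta * 180 / pi
  label <- if (deg <= oblique_band + 1e-9) "longitudinal"
  else if (deg >= 90 - oblique_band - 1e-9) "transverse"
  else "oblique"
  list(label = label, plane_angle = delta)
}
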
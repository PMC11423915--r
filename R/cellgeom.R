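# Per-cell geometric descriptors.
#
# Each descriptor works on a cell_contour (or a bare vertex matrix): area and
# perimeter from the polygon itself; elongation and main-axis angle from the
# minimal bounding rectangle (MBR) of the convex hull; rectangularity as the
# overlap proportion between the cell and its MBR rescaled to equal area.

.contour_vertices <- function(x) {
  if (inherits(x, "cell_contour")) return(x$vertices)
  v <- as.matrix(x)
  if (!is.numeric(v) || ncol(v) != 2L || nrow(v) < 3L) {
    stop("expected a cell_contour or an n x 2 vertex matrix", call. = FALSE)
  }
  v
}

#' Polygon surface area
#'
#' @param contour a \code{\link{cell_contour}} or an n x 2 vertex matrix
#'   (um, implicit closure).
#' @return Area in um^2 (positive).
#' @export
polygon_area <- function(contour) {
  v <- .contour_vertices(contour)
  a <- abs(.signed_area(v))
  if (a < .GEOM_TOL^2) stop("degenerate polygon: zero area", call. = FALSE)
  a
}

#' Polygon perimeter
#'
#' Sum of edge lengths including the implicit closing edge.
#'
#' @inheritParams polygon_area
#' @return Perimeter in um.
#' @export
polygon_perimeter <- function(contour) {
  v <- .contour_vertices(contour)
  if (abs(.signed_area(v)) < .GEOM_TOL^2) {
    stop("degenerate polygon: zero area", call. = FALSE)
  }
  .perimeter(v)
}

#' Convex hull of a contour
#'
#' @inheritParams polygon_area
#' @return A \code{\link{cell_contour}} tracing the convex hull
#'   counter-clockwise; its vertices are a subset of the input vertices.
#' @export
convex_hull <- function(contour) {
  v <- .contour_vertices(contour)
  idx <- grDevices::chull(v[, 1L], v[, 2L])
  h <- v[idx, , drop = FALSE]
  if (nrow(h) < 3L || abs(.signed_area(h)) < .GEOM_TOL^2) {
    stop("degenerate contour: all points collinear", call. = FALSE)
  }
  if (.signed_area(h) < 0) h <- h[rev(seq_len(nrow(h))), , drop = FALSE]
  id <- if (inherits(contour, "cell_contour")) contour$cell_id else "hull"
  cell_contour(h, id)
}

#' Minimal bounding rectangle
#'
#' Smallest-area rectangle enclosing a convex polygon, found by rotating
#' calipers: the optimum has one side collinear with a hull edge, so only
#' hull-edge orientations need to be examined.  Ties in area (within 1e-12
#' relative) are broken by the smallest angle in [0, pi).
#'
#' @param hull a convex \code{\link{cell_contour}} (e.g. from
#'   \code{\link{convex_hull}}) or vertex matrix; non-convex input is
#'   replaced by its convex hull.
#' @return An object of class \code{mbr}: list with \code{centre} (um),
#'   \code{angle} (radians in [0, pi), orientation of the long side),
#'   \code{length} (um, long side), \code{width} (um, short side).
#' @export
min_bounding_rectangle <- function(hull) {
  h <- convex_hull(hull)$vertices
  n <- nrow(h)
  edges <- rbind(h[-1L, , drop = FALSE], h[1L, , drop = FALSE]) - h
  best <- NULL
  for (i in seq_len(n)) {
    e <- edges[i, ]
    len <- sqrt(sum(e^2))
    if (len < .GEOM_TOL) next
    u <- e / len
    w <- c(-u[2L], u[1L])
    pu <- h %*% u
    pw <- h %*% w
    du <- max(pu) - min(pu)
    dw <- max(pw) - min(pw)
    area <- du * dw
    # long-side orientation folded into [0, pi)
    ang <- if (du >= dw) atan2(u[2L], u[1L]) else atan2(w[2L], w[1L])
    ang <- unname(ang) %% pi
    if (pi - ang < 1e-12) ang <- 0
    cand <- list(area = area,
                 length = max(du, dw), width = min(du, dw),
                 angle = ang,
                 centre = c((max(pu) + min(pu)) / 2 * u[1L] +
                              (max(pw) + min(pw)) / 2 * w[1L],
                            (max(pu) + min(pu)) / 2 * u[2L] +
                              (max(pw) + min(pw)) / 2 * w[2L]))
    if (is.null(best) ||
        cand$area < best$area * (1 - 1e-12) ||
        (cand$area <= best$area * (1 + 1e-12) && cand$angle < best$angle)) {
      best <- cand
    }
  }
  if (is.null(best)) stop("degenerate hull", call. = FALSE)
  structure(list(centre = unname(best$centre), angle = best$angle,
                 length = unname(best$length), width = unname(best$width)),
            class = "mbr")
}

#' @export
print.mbr <- function(x, ...) {
  cat(sprintf("<mbr> %.4g x %.4g um at %.1f deg, centre (%.4g, %.4g)\n",
              x$length, x$width, x$angle * 180 / pi,
              x$centre[1L], x$centre[2L]))
  invisible(x)
}

# Corner vertices (CCW) of an mbr, optionally rescaled about its centre.
.mbr_corners <- function(mbr, scale = 1) {
  u <- c(cos(mbr$angle), sin(mbr$angle))
  w <- c(-u[2L], u[1L])
  hl <- mbr$length / 2 * scale
  hw <- mbr$width / 2 * scale
  ctr <- mbr$centre
  rbind(ctr - hl * u - hw * w,
        ctr + hl * u - hw * w,
        ctr + hl * u + hw * w,
        ctr - hl * u + hw * w)
}

#' Rectangularity of a cell
#'
#' Shape score in (0, 1] quantifying how close a cell is to a rectangle with
#' perpendicular sides.  The MBR is uniformly rescaled about its own centre
#' to the cell's area, and the score is the proportion of the cell's surface
#' overlapping that equal-area rectangle:
#' \deqn{R = area(cell \cap MBR^{rescaled}) / area(cell).}
#' A perfect rectangle scores exactly 1; the score decreases as interior
#' angles deviate from 90 degrees (a sheared parallelogram or an irregular
#' polygon overlaps its equal-area MBR less).  Invariant under rigid motions
#' and uniform scaling.
#'
#' @inheritParams polygon_area
#' @param mbr optionally, the precomputed \code{\link{min_bounding_rectangle}}
#'   of the contour's convex hull.
#' @return Rectangularity in (0, 1].
#' @export
rectangularity <- function(contour, mbr = NULL) {
  v <- .contour_vertices(contour)
  if (.signed_area(v) < 0) v <- v[rev(seq_len(nrow(v))), , drop = FALSE]
  if (is.null(mbr)) mbr <- min_bounding_rectangle(v)
  a_cell <- polygon_area(v)
  a_mbr <- mbr$length * mbr$width
  rect <- .mbr_corners(mbr, scale = sqrt(a_cell / a_mbr))
  clipped <- .clip_polygon_convex(v, rect)
  if (nrow(clipped) < 3L) return(0)
  min(1, abs(.signed_area(clipped)) / a_cell)
}

#' Per-cell morphometrics table
#'
#' One record per cell: surface area, perimeter, convex-hull area, MBR
#' dimensions, elongation (MBR length/width), main-axis angle (from the MBR)
#' and rectangularity.  Mirrors the per-cell supplementary-table layout; when
#' a neighbour graph is supplied, the per-cell neighbour count is appended.
#'
#' @param lam a \code{\link{lamina}}.
#' @param graph optional \code{\link{neighbour_graph}} of the same lamina.
#' @return A data frame with one row per cell, in lamina order.
#' @examples
#' g <- generate_lamina(rows = 3, cols = 3, cell_size = 10)
#' cm <- cell_morphometrics(g$lamina)
#' summary(cm$rectangularity)
#' @export
cell_morphometrics <- function(lam, graph = NULL) {
  stopifnot(inherits(lam, "lamina"))
  rows <- lapply(lam$cells, function(cc) {
    rec <- tryCatch({
      hull <- convex_hull(cc)
      mbr <- min_bounding_rectangle(hull)
      list(area = polygon_area(cc),
           perimeter = polygon_perimeter(cc),
           hull_area = polygon_area(hull),
           mbr = mbr,
           rect = rectangularity(cc, mbr))
    }, error = function(e) {
      stop("cell '", cc$cell_id, "': ", conditionMessage(e), call. = FALSE)
    })
    data.frame(embryo_id = lam$embryo_id,
               cell_id = cc$cell_id,
               area_um2 = rec$area,
               perimeter_um = rec$perimeter,
               hull_area_um2 = rec$hull_area,
               mbr_length_um = rec$mbr$length,
               mbr_width_um = rec$mbr$width,
               elongation = rec$mbr$length / rec$mbr$width,
               rectangularity = rec$rect,
               main_axis_angle = rec$mbr$angle,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(graph)) {
    counts <- neighbour_counts(graph)
    out$n_neighbours <- as.integer(counts[out$cell_id])
  }
  out
}
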
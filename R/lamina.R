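#' Cell contour
#'
#' A closed, simple polygon tracing one cell wall, in micrometres.  The first
#' vertex is not repeated; closure is implicit.  On construction, consecutive
#' vertices closer than 1e-9 um are merged (hand-traced paths contain
#' duplicates) and the orientation is normalised to counter-clockwise.
#'
#' @param vertices numeric matrix with two columns (x, y in um) and at least
#'   three rows, or a data frame coercible to one.
#' @param cell_id identifier for the cell (coerced to character).
#' @return An object of class \code{cell_contour}: a list with elements
#'   \code{cell_id} and \code{vertices}.
#' @examples
#' sq <- cell_contour(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)), "c1")
#' polygon_area(sq)
#' @export
cell_contour <- function(vertices, cell_id = "cell") {
  v <- as.matrix(vertices)
  if (!is.numeric(v) || ncol(v) != 2L) {
    stop("`vertices` must be a numeric matrix with two columns", call. = FALSE)
  }
  if (anyNA(v) || any(!is.finite(v))) {
    stop("cell '", cell_id, "': non-finite vertex coordinates", call. = FALSE)
  }
  # drop an explicit closing vertex, then merge near-coincident neighbours
  if (nrow(v) > 1L && sqrt(sum((v[1L, ] - v[nrow(v), ])^2)) < .GEOM_TOL) {
    v <- v[-nrow(v), , drop = FALSE]
  }
  keep <- rep(TRUE, nrow(v))
  for (i in seq_len(nrow(v))[-1L]) {
    prev <- max(which(keep[seq_len(i - 1L)]))
    if (sqrt(sum((v[i, ] - v[prev, ])^2)) < .GEOM_TOL) keep[i] <- FALSE
  }
  v <- v[keep, , drop = FALSE]
  if (nrow(v) < 3L) {
    stop("cell '", cell_id, "': fewer than 3 distinct vertices", call. = FALSE)
  }
  if (!.is_simple_polygon(v)) {
    stop("cell '", cell_id, "': self-intersecting polygon", call. = FALSE)
  }
  a <- .signed_area(v)
  if (abs(a) < .GEOM_TOL^2) {
    stop("cell '", cell_id, "': degenerate polygon (zero area)", call. = FALSE)
  }
  if (a < 0) v <- v[rev(seq_len(nrow(v))), , drop = FALSE]
  dimnames(v) <- list(NULL, c("x", "y"))
  structure(list(cell_id = as.character(cell_id), vertices = v),
            class = "cell_contour")
}

#' @export
print.cell_contour <- function(x, ...) {
  cat("<cell_contour> id:", x$cell_id, "-", nrow(x$vertices), "vertices,",
      format(abs(.signed_area(x$vertices)), digits = 4), "um^2\n")
  invisible(x)
}

#' Lamina: one embryo at one time point
#'
#' The sample unit of the analysis: a set of closed cell contours with
#' physical scale and metadata.  The early kelp sporophyte grows as a flat
#' monolayer (the blade or lamina), so a set of 2-D wall outlines captures
#' its full tissue geometry.
#'
#' @param cells list of \code{\link{cell_contour}} objects (non-empty).
#' @param embryo_id identifier for the embryo.
#' @param stage_group one of \code{"E0"}, \code{"E1"}, \code{"E2"},
#'   \code{"E4"}, \code{"E8"}, \code{"PhII"}, \code{"intact"}: the
#'   developmental stage at which the embryo was severed from the maternal
#'   stalk ("intact" = never severed).
#' @param time_h hours since the experiment reference, or \code{NA}.
#' @param scale micrometres per drawing unit used at ingest (recorded for
#'   provenance; coordinates are already in um).
#' @return An object of class \code{lamina}.
#' @export
lamina <- function(cells, embryo_id = "embryo", stage_group = "intact",
                   time_h = NA_real_, scale = 1) {
  stage_group <- match.arg(stage_group, .STAGE_GROUPS)
  if (!is.list(cells) || length(cells) == 0L) {
    stop("`cells` must be a non-empty list of cell_contour objects",
         call. = FALSE)
  }
  if (!all(vapply(cells, inherits, logical(1L), "cell_contour"))) {
    stop("all elements of `cells` must be cell_contour objects", call. = FALSE)
  }
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) ||
      scale <= 0) {
    stop("`scale` must be a strictly positive number", call. = FALSE)
  }
  ids <- vapply(cells, function(c) c$cell_id, character(1L))
  if (anyDuplicated(ids)) {
    stop("duplicated cell ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  structure(list(embryo_id = as.character(embryo_id),
                 stage_group = stage_group,
                 time_h = as.numeric(time_h),
                 scale = as.numeric(scale),
                 cells = cells),
            class = "lamina")
}

.STAGE_GROUPS <- c("E0", "E1", "E2", "E4", "E8", "PhII", "intact")

#' @export
print.lamina <- function(x, ...) {
  cat("<lamina>", x$embryo_id, "-", length(x$cells), "cells, stage",
      x$stage_group,
      if (is.finite(x$time_h)) paste0("(t = ", x$time_h, " h)") else "",
      "\n")
  invisible(x)
}

#' @export
length.lamina <- function(x) length(x$cells)

#' Number of cells in a lamina
#' @param lam a \code{\link{lamina}}.
#' @return Integer cell count.
#' @export
n_cells <- function(lam) {
  stopifnot(inherits(lam, "lamina"))
  length(lam$cells)
}

# All cell ids of a lamina, in order.
.cell_ids <- function(lam) {
  vapply(lam$cells, function(c) c$cell_id, character(1L))
}
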
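# Tissue topology from contour geometry.
#
# Each cell is traced as its own closed outline, so a wall shared by two
# adjacent cells appears twice, as two nearly-coincident polylines.
# Adjacency is recovered geometrically: the shared wall length between cells
# a and b is the length of a's boundary lying within a proximity tolerance
# of b's boundary (and vice versa; the two directed measurements are
# averaged so the measure is symmetric).  Two cells are neighbours when they
# share at least `min_shared` micrometres of wall; the default 0.2 um
# (200 nm) is the field's convention and is exposed as a parameter.

# Directed measure: length of the boundary of `va` within `tol` of the
# boundary of `vb`.  For each edge of a, the set of points within tol of a
# segment of b is a capsule (slab rectangle + two end disks), each convex,
# so each contributes at most three t-intervals; their union over all edges
# of b is accumulated and measured exactly.
.directed_shared_length <- function(va, vb, tol) {
  ea_from <- va
  ea_to <- rbind(va[-1L, , drop = FALSE], va[1L, , drop = FALSE])
  eb_from <- vb
  eb_to <- rbind(vb[-1L, , drop = FALSE], vb[1L, , drop = FALSE])
  bb_b <- c(min(vb[, 1L]) - tol, max(vb[, 1L]) + tol,
            min(vb[, 2L]) - tol, max(vb[, 2L]) + tol)
  total <- 0
  for (i in seq_len(nrow(va))) {
    p <- ea_from[i, ]
    q <- ea_to[i, ]
    L <- sqrt(sum((q - p)^2))
    if (L < .GEOM_TOL) next
    # quick reject: edge bbox vs expanded bbox of b
    if (max(p[1L], q[1L]) < bb_b[1L] || min(p[1L], q[1L]) > bb_b[2L] ||
        max(p[2L], q[2L]) < bb_b[3L] || min(p[2L], q[2L]) > bb_b[4L]) next
    d <- q - p
    ivs <- NULL
    for (j in seq_len(nrow(vb))) {
      q0 <- eb_from[j, ]
      q1 <- eb_to[j, ]
      ivs <- rbind(ivs,
                   .seg_slab_interval(p, d, q0, q1, tol),
                   .seg_disk_interval(p, d, q0, tol),
                   .seg_disk_interval(p, d, q1, tol))
    }
    total <- total + .interval_union_length(ivs) * L
  }
  total
}

#' Shared cell-wall length between two contours
#'
#' Total boundary length that the two cells hold in common, i.e. the portion
#' of one boundary lying within \code{proximity_tol} of the other.  The
#' tolerance absorbs the near-coincidence of independently hand-traced
#' duplicate walls; it is distinct from the minimum-shared-length criterion
#' used to declare neighbours (see \code{\link{neighbour_graph}}).
#'
#' @param a,b \code{\link{cell_contour}} objects (or vertex matrices).
#' @param proximity_tol coincidence tolerance in um (default 0.05).
#' @return Shared wall length in um; symmetric in its arguments.
#' @export
shared_wall_length <- function(a, b, proximity_tol = 0.05) {
  va <- .contour_vertices(a)
  vb <- .contour_vertices(b)
  if (!is.numeric(proximity_tol) || proximity_tol <= 0) {
    stop("`proximity_tol` must be positive", call. = FALSE)
  }
  (.directed_shared_length(va, vb, proximity_tol) +
     .directed_shared_length(vb, va, proximity_tol)) / 2
}

#' Cell-neighbour graph of a lamina
#'
#' Two cells are neighbours when they share at least \code{min_shared}
#' micrometres of cell wall (default 0.2 um = 200 nm, modifiable).
#' Candidate pairs are pruned by bounding boxes expanded by
#' \code{proximity_tol}, which cannot change the result because cells
#' further apart than the tolerance share no wall.
#'
#' @param lam a \code{\link{lamina}}.
#' @param min_shared minimum shared wall length (um) for an edge.
#' @param proximity_tol coincidence tolerance passed to
#'   \code{\link{shared_wall_length}}.
#' @return An object of class \code{neighbour_graph}: list with
#'   \code{cell_ids} and an \code{edges} data frame
#'   (\code{cell_a}, \code{cell_b}, \code{shared_um}).
#' @examples
#' g <- generate_lamina(rows = 3, cols = 3, cell_size = 10)
#' ng <- neighbour_graph(g$lamina)
#' neighbour_counts(ng)
#' @export
neighbour_graph <- function(lam, min_shared = 0.2, proximity_tol = 0.05) {
  stopifnot(inherits(lam, "lamina"))
  if (min_shared <= 0) stop("`min_shared` must be positive", call. = FALSE)
  ids <- .cell_ids(lam)
  nc <- length(ids)
  boxes <- t(vapply(lam$cells, function(cc) {
    v <- cc$vertices
    c(min(v[, 1L]), max(v[, 1L]), min(v[, 2L]), max(v[, 2L]))
  }, numeric(4L)))
  ea <- integer(0); eb <- integer(0); ew <- numeric(0)
  if (nc > 1L) {
    for (i in seq_len(nc - 1L)) {
      for (j in (i + 1L):nc) {
        # prune: expanded bounding boxes must overlap
        if (boxes[i, 1L] > boxes[j, 2L] + proximity_tol ||
            boxes[j, 1L] > boxes[i, 2L] + proximity_tol ||
            boxes[i, 3L] > boxes[j, 4L] + proximity_tol ||
            boxes[j, 3L] > boxes[i, 4L] + proximity_tol) next
        s <- shared_wall_length(lam$cells[[i]], lam$cells[[j]],
                                proximity_tol)
        if (s >= min_shared) {
          ea <- c(ea, i); eb <- c(eb, j); ew <- c(ew, s)
        }
      }
    }
  }
  structure(list(cell_ids = ids,
                 edges = data.frame(cell_a = ids[ea], cell_b = ids[eb],
                                    shared_um = ew,
                                    stringsAsFactors = FALSE),
                 min_shared = min_shared,
                 proximity_tol = proximity_tol),
            class = "neighbour_graph")
}

#' @export
print.neighbour_graph <- function(x, ...) {
  cat("<neighbour_graph>", length(x$cell_ids), "cells,",
      nrow(x$edges), "shared walls (min", x$min_shared, "um)\n")
  invisible(x)
}

#' Per-cell neighbour counts
#'
#' @param graph a \code{\link{neighbour_graph}}.
#' @return Named integer vector of neighbour counts, one per cell.
#' @export
neighbour_counts <- function(graph) {
  stopifnot(inherits(graph, "neighbour_graph"))
  counts <- stats::setNames(integer(length(graph$cell_ids)), graph$cell_ids)
  if (nrow(graph$edges) > 0L) {
    t1 <- table(graph$edges$cell_a)
    t2 <- table(graph$edges$cell_b)
    counts[names(t1)] <- counts[names(t1)] + as.integer(t1)
    counts[names(t2)] <- counts[names(t2)] + as.integer(t2)
  }
  counts
}

#' Neighbour-count distribution
#'
#' Histogram of per-cell neighbour counts over the bins
#' \{1, 2, 3, 4, >=5\} used for topology comparisons between stage groups.
#' Isolated cells (0 neighbours) get their own bin with a warning, since a
#' monolayer should not contain any.
#'
#' @param graph a \code{\link{neighbour_graph}}.
#' @return Named integer vector of bin counts summing to the number of
#'   cells, with an attribute \code{proportions}.
#' @export
neighbour_count_distribution <- function(graph) {
  counts <- neighbour_counts(graph)
  if (length(counts) == 0L) stop("empty graph", call. = FALSE)
  bins <- c("1", "2", "3", "4", ">=5")
  out <- stats::setNames(integer(5L), bins)
  for (k in counts) {
    if (k >= 5L) out[">=5"] <- out[">=5"] + 1L
    else if (k >= 1L) out[as.character(k)] <- out[as.character(k)] + 1L
  }
  n0 <- sum(counts == 0L)
  if (n0 > 0L) {
    warning(n0, " isolated cell(s) with no neighbours", call. = FALSE)
    out <- c("0" = n0, out)
  }
  attr(out, "proportions") <- out / sum(out)
  out
}
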
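# SVG segmentation I/O.
#
# The segmentation dialect: one SVG file per embryo per time point; every
# closed `path` (ending in Z), `polygon` or `rect` element is one cell wall
# outline.  Inkscape, used for manual tracing, emits exactly these.  Other
# graphical elements are ignored with a warning; open tracings (`polyline`
# or a path without Z) abort with an error naming the offending element,
# since a silent drop would change the cell count.  SVG y grows downward, so
# y is negated at ingest to work in a right-handed frame; physical scale
# (um per drawing unit) is supplied by the caller, never read from SVG
# metadata.

#' Read a segmented lamina from an SVG file
#'
#' @param path path to an SVG 1.1 file.
#' @param scale micrometres per SVG drawing unit; strictly positive.
#' @param embryo_id,stage_group,time_h metadata attached to the lamina (see
#'   \code{\link{lamina}}).
#' @return A \code{\link{lamina}} with one \code{\link{cell_contour}} per
#'   closed path, coordinates in micrometres, contours counter-clockwise.
#' @examples
#' f <- tempfile(fileext = ".svg")
#' lam <- generate_lamina(rows = 2, cols = 2, cell_size = 10)$lamina
#' write_lamina_svg(lam, f)
#' lam2 <- read_lamina_svg(f, scale = 1)
#' n_cells(lam2)
#' @export
read_lamina_svg <- function(path, scale = 1, embryo_id = NULL,
                            stage_group = "intact", time_h = NA_real_) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) ||
      scale <= 0) {
    stop("`scale` must be a strictly positive number", call. = FALSE)
  }
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("cannot parse SVG file '", path,
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
  if (is.null(embryo_id)) {
    embryo_id <- sub("\\.svg$", "", basename(path), ignore.case = TRUE)
  }
  nodes <- xml2::xml_find_all(doc, ".//*")
  cells <- list()
  ignored <- character(0)
  k <- 0L
  for (node in nodes) {
    tag <- xml2::xml_name(node)
    id <- xml2::xml_attr(node, "id")
    verts <- switch(tag,
      path = {
        d <- xml2::xml_attr(node, "d")
        if (is.na(d)) {
          stop("path element '", if (is.na(id)) "<no id>" else id,
               "' has no 'd' attribute", call. = FALSE)
        }
        .svg_path_vertices(d, id)
      },
      polygon = {
        pts <- xml2::xml_attr(node, "points")
        .svg_points_vertices(pts, id)
      },
      rect = .svg_rect_vertices(node),
      polyline = stop("open polyline element '",
                      if (is.na(id)) "<no id>" else id,
                      "' is not a closed cell contour", call. = FALSE),
      {
        if (tag %in% c("line", "circle", "ellipse", "text", "image")) {
          ignored <- c(ignored, tag)
        }
        NULL
      }
    )
    if (is.null(verts)) next
    if (is.list(verts) && !is.matrix(verts)) {
      sub_list <- verts
    } else {
      sub_list <- list(verts)
    }
    for (verts_i in sub_list) {
      k <- k + 1L
      cid <- if (!is.na(id) && length(sub_list) == 1L) id else {
        if (!is.na(id)) paste0(id, ".", k) else paste0("cell_", k)
      }
      v <- verts_i * scale
      v[, 2L] <- -v[, 2L]  # right-handed frame
      cells[[k]] <- cell_contour(v, cid)
    }
  }
  if (length(ignored) > 0L) {
    warning("ignored non-cell SVG elements: ",
            paste(sort(unique(ignored)), collapse = ", "), call. = FALSE)
  }
  if (length(cells) == 0L) {
    stop("no closed cell contours found in '", path, "'", call. = FALSE)
  }
  lamina(cells, embryo_id = embryo_id, stage_group = stage_group,
         time_h = time_h, scale = scale)
}

# Parse an SVG path `d` attribute into one vertex matrix per closed subpath.
# Supports straight-line commands (M/m, L/l, H/h, V/v, Z/z); curve commands
# abort, since a curved wall cannot be represented as a polygon without a
# sampling policy.
.svg_path_vertices <- function(d, id = NA_character_) {
  label <- if (is.na(id)) "<no id>" else id
  toks <- regmatches(d, gregexpr("[MmLlHhVvZzCcSsQqTtAa]|-?[0-9.eE+]+", d))[[1]]
  subpaths <- list()
  cur <- NULL
  closed <- FALSE
  pos <- c(0, 0)
  i <- 1L
  cmd <- ""
  take <- function(n) {
    if (i + n - 1L > length(toks)) {
      stop("path '", label, "': truncated coordinate data", call. = FALSE)
    }
    vals <- as.numeric(toks[i:(i + n - 1L)])
    if (anyNA(vals)) {
      stop("path '", label, "': malformed coordinate", call. = FALSE)
    }
    i <<- i + n
    vals
  }
  flush_subpath <- function() {
    if (!is.null(cur)) {
      if (!closed) {
        stop("open (non-closed) subpath in path '", label, "'", call. = FALSE)
      }
      subpaths[[length(subpaths) + 1L]] <<- cur
    }
    cur <<- NULL
    closed <<- FALSE
  }
  while (i <= length(toks)) {
    t <- toks[i]
    if (grepl("^[A-Za-z]$", t)) {
      if (t %in% c("C", "c", "S", "s", "Q", "q", "T", "t", "A", "a")) {
        stop("path '", label, "': unsupported curve command '", t,
             "' (cell walls must be polygonal)", call. = FALSE)
      }
      cmd <- t
      i <- i + 1L
      if (cmd %in% c("Z", "z")) {
        closed <- TRUE
        if (!is.null(cur)) pos <- cur[1L, ]
        flush_subpath()
      }
      next
    }
    if (cmd == "") stop("path '", label, "': coordinates before any command",
                        call. = FALSE)
    xy <- switch(cmd,
      M = , L = take(2L),
      m = , l = pos + take(2L),
      H = c(take(1L), pos[2L]),
      h = c(pos[1L] + take(1L), pos[2L]),
      V = c(pos[1L], take(1L)),
      v = c(pos[1L], pos[2L] + take(1L)),
      stop("path '", label, "': unsupported command '", cmd, "'",
           call. = FALSE)
    )
    if (cmd %in% c("M", "m")) {
      flush_subpath()  # an unclosed previous subpath errors here
      cur <- matrix(xy, ncol = 2L)
      # subsequent pairs after a moveto are implicit linetos
      cmd <- if (cmd == "M") "L" else "l"
    } else {
      cur <- rbind(cur, xy)
    }
    pos <- xy
  }
  if (!is.null(cur)) {
    stop("open (non-closed) subpath in path '", label, "'", call. = FALSE)
  }
  if (length(subpaths) == 0L) {
    stop("path '", label, "' contains no closed subpath", call. = FALSE)
  }
  if (length(subpaths) == 1L) subpaths[[1L]] else subpaths
}

.svg_points_vertices <- function(points, id = NA_character_) {
  if (is.na(points)) {
    stop("polygon element '", if (is.na(id)) "<no id>" else id,
         "' has no 'points' attribute", call. = FALSE)
  }
  vals <- as.numeric(strsplit(trimws(points), "[,[:space:]]+")[[1]])
  if (anyNA(vals) || length(vals) %% 2L != 0L) {
    stop("polygon '", if (is.na(id)) "<no id>" else id,
         "': malformed points list", call. = FALSE)
  }
  matrix(vals, ncol = 2L, byrow = TRUE)
}

.svg_rect_vertices <- function(node) {
  g <- function(a) {
    v <- suppressWarnings(as.numeric(xml2::xml_attr(node, a)))
    if (is.na(v)) if (a %in% c("x", "y")) 0 else NA_real_ else v
  }
  x <- g("x"); y <- g("y"); w <- g("width"); h <- g("height")
  if (is.na(w) || is.na(h)) {
    stop("rect element without width/height", call. = FALSE)
  }
  cbind(c(x, x + w, x + w, x), c(y, y, y + h, y + h))
}

#' Write a lamina to an SVG file
#'
#' Writes one closed \code{path} element per cell.  Coordinates are divided
#' by the lamina's scale and the y axis flipped back to SVG convention, so
#' \code{read_lamina_svg(write_lamina_svg(lam), scale = lam$scale)}
#' reproduces all vertices to within 1e-6 um.
#'
#' @param lam a \code{\link{lamina}}.
#' @param path output file path.
#' @param fill optional character vector of per-cell fill colours, one per
#'   cell (default: unfilled outlines).
#' @return The output path, invisibly.
#' @export
write_lamina_svg <- function(lam, path, fill = NULL) {
  stopifnot(inherits(lam, "lamina"))
  nc <- length(lam$cells)
  if (!is.null(fill) && length(fill) != nc) {
    stop("`fill` must have one colour per cell (", nc, "), got ",
         length(fill), call. = FALSE)
  }
  paths <- character(nc)
  all_v <- do.call(rbind, lapply(lam$cells, function(c) c$vertices))
  for (k in seq_len(nc)) {
    v <- lam$cells[[k]]$vertices / lam$scale
    v[, 2L] <- -v[, 2L]
    d <- paste0("M ", paste(sprintf("%.8f,%.8f", v[, 1L], v[, 2L]),
                            collapse = " L "), " Z")
    style <- if (is.null(fill)) {
      "fill:none;stroke:#000000;stroke-width:0.2"
    } else {
      paste0("fill:", fill[k], ";stroke:#000000;stroke-width:0.2")
    }
    paths[k] <- sprintf('  <path id="%s" d="%s" style="%s"/>',
                        lam$cells[[k]]$cell_id, d, style)
  }
  vb <- all_v / lam$scale
  vb[, 2L] <- -vb[, 2L]
  pad <- 2
  x0 <- min(vb[, 1L]) - pad; y0 <- min(vb[, 2L]) - pad
  w <- diff(range(vb[, 1L])) + 2 * pad
  h <- diff(range(vb[, 2L])) + 2 * pad
  txt <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" ',
                   'viewBox="%.6f %.6f %.6f %.6f">'), x0, y0, w, h),
    paths,
    "</svg>")
  ok <- tryCatch({
    writeLines(txt, path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write SVG to '", path, "'", call. = FALSE)
  invisible(path)
}

#' Read an experiment manifest
#'
#' The sidecar metadata convention: one CSV per experiment with columns
#' \code{embryo_id}, \code{file}, \code{stage_group}, \code{time_h},
#' \code{scale_um_per_unit}.  Relative \code{file} paths are resolved
#' against the manifest's directory.
#'
#' @param path path to the manifest CSV.
#' @return A data frame with the columns above, \code{file} resolved.
#' @export
read_lamina_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("embryo_id", "file", "stage_group", "time_h", "scale_um_per_unit")
  missing_cols <- setdiff(need, names(m))
  if (length(missing_cols) > 0L) {
    stop("manifest lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  rel <- !grepl("^(/|[A-Za-z]:)", m$file)
  m$file[rel] <- file.path(dirname(path), m$file[rel])
  m
}
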
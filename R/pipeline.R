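# End-to-end pipeline: manifest of segmented laminae -> per-cell table,
# per-blade table, and the per-window statistical comparisons of every
# severed stage group against the intact controls.

#' Pipeline configuration
#'
#' @param min_shared minimum shared wall length (um) for two cells to count
#'   as neighbours (default 0.2 um = 200 nm).
#' @param proximity_tol coincidence tolerance (um) for matching duplicated
#'   hand-traced walls.
#' @param oblique_band division-orientation band half-width in degrees.
#' @param growth_window fitting window (hours) around the phase I -> II
#'   transition for growth-rate regression.
#' @param heatmaps also paint per-cell area heatmaps when an output
#'   directory is given.
#' @param seed integer seed recorded in the run log.
#' @return A list of class \code{run_config}.
#' @export
run_config <- function(min_shared = 0.2, proximity_tol = 0.05,
                       oblique_band = 30, growth_window = c(-48, 72),
                       heatmaps = FALSE, seed = NULL) {
  stopifnot(min_shared > 0, proximity_tol > 0)
  structure(list(min_shared = min_shared, proximity_tol = proximity_tol,
                 oblique_band = oblique_band,
                 growth_window = growth_window,
                 heatmaps = heatmaps, seed = seed),
            class = "run_config")
}

# Per-window, per-stage-group contrasts against the intact controls:
# cell scalars pooled across embryos -> Welch t; blade scalars (one value
# per embryo) -> Mann-Whitney; neighbour-count bins -> chi-square.
.compare_groups <- function(cell_tab, blade_tab) {
  out <- list()
  for (w in unique(blade_tab$window)) {
    bw <- blade_tab[blade_tab$window == w, , drop = FALSE]
    cw <- cell_tab[cell_tab$window == w, , drop = FALSE]
    groups <- setdiff(unique(bw$stage_group), "intact")
    for (g in groups) {
      for (metric in c("area_um2", "rectangularity", "elongation")) {
        a <- cw[cw$stage_group == "intact", metric]
        b <- cw[cw$stage_group == g, metric]
        if (length(a) >= 2L && length(b) >= 2L) {
          row <- tryCatch(
            welch_t(b, a, metric = paste0("cell_", metric),
                    group_a = g, group_b = "intact"),
            error = function(e) {
              warning("skipping cell_", metric, " (", g, " vs intact, ",
                      w, "): ", conditionMessage(e), call. = FALSE)
              NULL
            })
          if (!is.null(row)) {
            row$window <- w
            out[[length(out) + 1L]] <- row
          }
        }
      }
      for (metric in c("lw_ratio", "blade_area_um2")) {
        a <- bw[bw$stage_group == "intact", metric]
        b <- bw[bw$stage_group == g, metric]
        if (length(a) >= 1L && length(b) >= 1L) {
          row <- mann_whitney(b, a, metric = paste0("blade_", metric),
                              group_a = g, group_b = "intact")
          row$window <- w
          out[[length(out) + 1L]] <- row
        }
      }
      if ("n_neighbours" %in% names(cw)) {
        bin <- function(k) ifelse(k >= 5L, ">=5", as.character(pmax(k, 1L)))
        lv <- c("1", "2", "3", "4", ">=5")
        ga <- factor(bin(cw$n_neighbours[cw$stage_group == "intact"]), lv)
        gb <- factor(bin(cw$n_neighbours[cw$stage_group == g]), lv)
        tab <- cbind(intact = table(ga), group = table(gb))
        colnames(tab) <- c("intact", g)
        nonzero <- rowSums(tab) > 0
        if (length(ga) > 0L && length(gb) > 0L && sum(nonzero) >= 2L) {
          row <- suppressWarnings(
            chi2_counts(tab, metric = "neighbour_counts",
                        group_a = g, group_b = "intact"))
          row$window <- w
          out[[length(out) + 1L]] <- row
        }
      }
    }
  }
  if (length(out) == 0L) return(NULL)
  res <- do.call(rbind, out)
  res[, c("metric", "window", "group_a", "group_b", "test", "statistic",
          "df", "p_value")]
}

#' Run the full morphometry pipeline
#'
#' Reads every lamina listed in a manifest, computes per-cell and per-blade
#' morphometrics and neighbour topology, and compares each severed stage
#' group against the intact controls within each developmental window
#' (cell metrics by Welch's t, blade metrics by Mann-Whitney,
#' neighbour-count distributions by chi-square).
#'
#' @param manifest a data frame (or path to a CSV) with columns
#'   \code{embryo_id}, \code{file}, \code{stage_group}, \code{time_h},
#'   \code{scale_um_per_unit} (see \code{\link{read_lamina_manifest}}).
#' @param out_dir optional output directory; when given, writes
#'   \code{cell_morphometrics.csv}, \code{blade_metrics.csv},
#'   \code{comparisons.csv}, a run log, and (if configured) per-embryo
#'   cell-area heatmap SVGs.
#' @param config a \code{\link{run_config}}.
#' @return List with \code{cells}, \code{blades}, \code{comparisons}
#'   (data frames; comparisons \code{NULL} when no intact group is
#'   present) and \code{n_comparisons}.
#' @export
run_pipeline <- function(manifest, out_dir = NULL, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  if (is.character(manifest)) manifest <- read_lamina_manifest(manifest)
  if (nrow(manifest) == 0L) stop("empty manifest", call. = FALSE)
  missing_files <- manifest$file[!file.exists(manifest$file)]
  if (length(missing_files) > 0L) {
    stop("manifest files not found: ",
         paste(missing_files, collapse = ", "), call. = FALSE)
  }
  cell_tabs <- list()
  blade_tabs <- list()
  laminae <- list()
  for (k in seq_len(nrow(manifest))) {
    row <- manifest[k, ]
    lam <- read_lamina_svg(row$file, scale = row$scale_um_per_unit,
                           embryo_id = row$embryo_id,
                           stage_group = row$stage_group,
                           time_h = row$time_h)
    graph <- neighbour_graph(lam, min_shared = config$min_shared,
                             proximity_tol = config$proximity_tol)
    cm <- cell_morphometrics(lam, graph)
    bm <- blade_metrics(lam)
    cm$stage_group <- lam$stage_group
    cm$window <- bm$window
    cell_tabs[[k]] <- cm
    blade_tabs[[k]] <- bm
    laminae[[row$embryo_id]] <- lam
  }
  cells <- do.call(rbind, cell_tabs)
  blades <- do.call(rbind, blade_tabs)
  rownames(cells) <- rownames(blades) <- NULL
  comparisons <- NULL
  if (!"intact" %in% blades$stage_group) {
    warning("no intact group in manifest; comparisons skipped",
            call. = FALSE)
  } else {
    comparisons <- .compare_groups(cells, blades)
  }
  n_comp <- if (is.null(comparisons)) 0L else nrow(comparisons)
  message("analysed ", nrow(blades), " laminae (", nrow(cells),
          " cells); ", n_comp, " statistical comparisons")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(cells, file.path(out_dir, "cell_morphometrics.csv"),
                     row.names = FALSE)
    utils::write.csv(blades, file.path(out_dir, "blade_metrics.csv"),
                     row.names = FALSE)
    if (!is.null(comparisons)) {
      utils::write.csv(comparisons, file.path(out_dir, "comparisons.csv"),
                       row.names = FALSE)
    }
    log_lines <- c(
      paste0("laminamorph ",
             as.character(utils::packageVersion("laminamorph"))),
      paste0("min_shared_um: ", config$min_shared),
      paste0("proximity_tol_um: ", config$proximity_tol),
      paste0("seed: ", if (is.null(config$seed)) "none" else config$seed),
      paste0("laminae: ", nrow(blades)),
      paste0("cells: ", nrow(cells)),
      paste0("comparisons: ", n_comp))
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
    if (isTRUE(config$heatmaps)) {
      for (id in names(laminae)) {
        lam <- laminae[[id]]
        vals <- cells$area_um2[cells$embryo_id == id]
        paint_heatmap(lam, vals,
                      file.path(out_dir, paste0(id, "_area_heatmap.svg")))
      }
    }
  }
  list(cells = cells, blades = blades, comparisons = comparisons,
       n_comparisons = n_comp)
}

#' Paint a per-cell metric heatmap onto a lamina SVG
#'
#' Fills each cell with a colour monotone in its metric value (low = cool,
#' high = hot), renders missing values neutral grey, and appends a legend
#' with the minimum and maximum.
#'
#' @param lam a \code{\link{lamina}}.
#' @param values numeric vector, one value per cell (NA = missing).
#' @param path output SVG path.
#' @param palette function taking an integer n and returning n colours
#'   ordered cool to hot.
#' @return The output path, invisibly.
#' @examples
#' g <- generate_lamina(rows = 3, cols = 3, cell_size = 10)
#' cm <- cell_morphometrics(g$lamina)
#' f <- tempfile(fileext = ".svg")
#' paint_heatmap(g$lamina, cm$area_um2, f)
#' @export
paint_heatmap <- function(lam, values, path,
                          palette = function(n) {
                            grDevices::hcl.colors(n, "YlOrRd", rev = TRUE)
                          }) {
  stopifnot(inherits(lam, "lamina"))
  nc <- length(lam$cells)
  if (length(values) != nc) {
    stop("`values` must have one entry per cell (", nc, "), got ",
         length(values), call. = FALSE)
  }
  cols <- rep("#bdbdbd", nc)  # neutral grey for missing values
  finite <- is.finite(values)
  ramp <- palette(256L)
  if (any(finite)) {
    lo <- min(values[finite]); hi <- max(values[finite])
    rel <- if (hi > lo) (values[finite] - lo) / (hi - lo) else
      rep(0.5, sum(finite))
    cols[finite] <- ramp[1L + round(rel * 255)]
  }
  write_lamina_svg(lam, path, fill = cols)
  # append a simple gradient legend inside the SVG
  if (any(finite)) {
    txt <- readLines(path)
    verts <- do.call(rbind, lapply(lam$cells, function(c) c$vertices))
    x0 <- min(verts[, 1L]) / lam$scale
    y0 <- -(min(verts[, 2L]) / lam$scale) + 4
    nseg <- 64L
    wseg <- (diff(range(verts[, 1L])) / lam$scale) / nseg
    segs <- vapply(seq_len(nseg), function(s) {
      sprintf(paste0('  <rect x="%.4f" y="%.4f" width="%.4f" height="2" ',
                     'style="fill:%s;stroke:none"/>'),
              x0 + (s - 1L) * wseg, y0, wseg * 1.05,
              ramp[1L + round((s - 1L) / (nseg - 1L) * 255)])
    }, character(1L))
    labels <- c(
      sprintf(paste0('  <text x="%.4f" y="%.4f" font-size="2.5">',
                     '%.3g</text>'), x0, y0 + 5.5, lo),
      sprintf(paste0('  <text x="%.4f" y="%.4f" font-size="2.5" ',
                     'text-anchor="end">%.3g</text>'),
              x0 + nseg * wseg, y0 + 5.5, hi))
    close_tag <- which(txt == "</svg>")
    txt <- c(txt[seq_len(close_tag - 1L)], segs, labels, "</svg>")
    writeLines(txt, path)
  }
  invisible(path)
}
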
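# SVG fixtures written programmatically at test time.

svg_wrap <- function(...) {
  c('<?xml version="1.0" encoding="UTF-8"?>',
    '<svg xmlns="http://www.w3.org/2000/svg" version="1.1" viewBox="0 0 100 100">',
    ...,
    "</svg>")
}

# Three closed 10x10-unit squares in a row, one per element kind.
fixture_three_squares <- function(path = tempfile(fileext = ".svg")) {
  writeLines(svg_wrap(
    '  <path id="sq1" d="M 0,0 L 10,0 L 10,10 L 0,10 Z"/>',
    '  <polygon id="sq2" points="12,0 22,0 22,10 12,10"/>',
    '  <rect id="sq3" x="24" y="0" width="10" height="10"/>'
  ), path)
  path
}

fixture_with_open_polyline <- function(path = tempfile(fileext = ".svg")) {
  writeLines(svg_wrap(
    '  <path id="sq1" d="M 0,0 L 10,0 L 10,10 L 0,10 Z"/>',
    '  <polyline id="stray" points="20,0 30,0 30,10"/>'
  ), path)
  path
}

fixture_with_open_path <- function(path = tempfile(fileext = ".svg")) {
  writeLines(svg_wrap(
    '  <path id="sq1" d="M 0,0 L 10,0 L 10,10 L 0,10 Z"/>',
    '  <path id="open1" d="M 20,0 L 30,0 L 30,10"/>'
  ), path)
  path
}

fixture_with_annotations <- function(path = tempfile(fileext = ".svg")) {
  writeLines(svg_wrap(
    '  <path id="sq1" d="M 0,0 L 10,0 L 10,10 L 0,10 Z"/>',
    '  <circle cx="50" cy="50" r="3"/>',
    '  <text x="5" y="5">label</text>'
  ), path)
  path
}

fixture_self_intersecting <- function(path = tempfile(fileext = ".svg")) {
  # bow-tie: edges cross
  writeLines(svg_wrap(
    '  <path id="bow" d="M 0,0 L 10,10 L 10,0 L 0,10 Z"/>'
  ), path)
  path
}

# Write any lamina plus a manifest CSV listing it and friends.
write_manifest <- function(laminae, dir = tempfile()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(laminae, function(lam) {
    f <- file.path(dir, paste0(lam$embryo_id, ".svg"))
    write_lamina_svg(lam, f)
    data.frame(embryo_id = lam$embryo_id, file = basename(f),
               stage_group = lam$stage_group, time_h = lam$time_h,
               scale_um_per_unit = 1, stringsAsFactors = FALSE)
  })
  manifest_path <- file.path(dir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), manifest_path, row.names = FALSE)
  manifest_path
}
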
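Package: laminamorph
Title: Quantitative Morphometry of Kelp Embryo Laminae
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Per-cell and per-blade geometric morphometry for manually
    segmented monolayer embryos of the kelp Saccharina latissima.  Reads
    cell-wall outlines from SVG segmentations, computes cell descriptors
    (area, perimeter, convex hull, minimal bounding rectangle, elongation,
    rectangularity), recovers tissue topology as a shared-wall neighbour
    graph, measures blade-level axes and length/width ratios, estimates
    cell-division rates and doubling times from time-lapse counts, and runs
    the group-comparison statistics used to phenotype embryos severed from
    the maternal stalk at successive developmental stages.  A synthetic
    lamina and division-simulation module provides ground-truth tessellations
    so every analysis stage is testable without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    grDevices,
    polyclip,
    stats,
    utils,
    xml2
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
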
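Package: tubecfm
Title: Pollen-Tube Micro-Indentation Analysis with a Pressurized
    Thin-Shell Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing cellular force microscopy (CFM)
    micro-indentation of pollen tubes grown in a microfluidic
    lab-on-a-chip. Includes a synthetic-data generator that produces
    force-displacement recordings with known ground truth, processing of
    raw curves into true force-indentation curves (contact detection and
    sensor-compliance cancellation), apparent-stiffness estimation with
    loading/unloading separation, cohort statistics and permutation group
    comparison, a forward model of indentation of a turgid thin-walled
    cylindrical shell (prestressed Donnell shallow-shell equations solved
    by double Fourier series, with an independent finite-difference
    oracle), and inversion of measured stiffness over physiological
    parameter ranges to bound the cell-wall Young's modulus. Chip-layout
    arithmetic for throughput planning is also provided.
License: MIT + file LICENSE
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    lhs,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
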
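Package: dicerruler
Title: Molecular Ruler Geometry of Insect Dicer-2 Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative structural analysis of the Dicer-2 "molecular ruler":
    reads protein structures in PDB format as tidy atom tables, transfers
    PAZ-pocket and RNase III catalytic-site annotations between orthologs by
    global sequence alignment, superimposes alpha-carbon coordinate sets with
    the Kabsch algorithm (global and per-domain RMSD), measures the
    centroid-to-centroid distances between the PAZ 3'/5' terminal
    nucleotide-binding pockets and the RNase III A/B catalytic centers, and
    converts those distances into predicted siRNA length classes through an
    anchored or least-squares calibration. A seeded generator of two-domain
    caliper scaffolds and ideal A-form dsRNA duplexes provides ground-truth
    structures for testing, and a configuration-driven pipeline produces
    replicate-aware tabular reports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
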
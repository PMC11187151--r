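Package: msipanel
Title: Microsatellite Instability Panel Design and MSI-H Calling from UMI-Seq Repeat Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and evaluating microsatellite instability (MSI)
    marker panels from UMI-tagged amplicon sequencing of tumor/normal pairs.
    Discovers candidate short-tandem-repeat loci in reference sequences (1-5 bp
    units occurring 7-13 times), collapses UMI read families to consensus
    repeat-length profiles, calls per-locus instability against a matched
    normal or a panel-of-normals baseline, runs a multi-stage locus-selection
    cascade (germline-polymorphism filter, dMMR-enrichment filter,
    hierarchical-then-K-means clustering, differential-cluster selection),
    exhaustively optimizes a loci combination under the "at least two unstable
    loci implies MSI-H" rule, and evaluates predictions against mismatch-repair
    status with standard confusion-matrix diagnostics. Ships a synthetic
    UMI-Seq cohort generator with PCR-stutter noise and planted somatic
    repeat-length shifts so the whole pipeline is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    data.table,
    jsonlite,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    Biostrings,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
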
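Package: isetscan
Title: Semi-Automated Microscopy Analysis of Filtration-Enriched Circulating Tumor Cells
Version: 0.1.0
Authors@R:
    person("ISET", "Scan Developers", email = "isetscan@example.org", role = c("aut", "cre"))
Description: Tools for semi-automated analysis of circulating tumor cells (CTCs)
    enriched on 8-micron-pore filtration membranes (ISET spots). Implements
    DAPI nucleus segmentation with intensity and area gating for automated
    DAPI+/CD45- candidate selection (including the three-pore cluster rule),
    eight-category phenotype classification with a reviewable image gallery,
    snick-fiducial relocation between staining rounds with cytomorphological
    CTC calling, break-apart FISH spot detection in z-stacks with
    multi-exposure fusion and per-setting detection-rate statistics, and a
    synthetic filter-spot simulator with known ground truth so the whole
    pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    grDevices,
    withr,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
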
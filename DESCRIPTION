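Package: rnaquant
Title: Per-Cell Quantification of Multiplex RNAscope Fluorescence Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies single-molecule fluorescent in situ hybridization
    (RNAscope) images at single-cell resolution. Nuclei are segmented from
    the DAPI channel by distance-transform watershed, probe channels are
    Gaussian-filtered and puncta are detected as prominence (noise-tolerance)
    maxima, nucleus masks are expanded by a fixed radius into disjoint cell
    territories, foci are counted per cell, and cells are called positive for
    a probe when they contain at least three foci. Region-level summaries
    (percent-positive heatmap tables, conditional co-expression percentages,
    co-expression class labels) and an applicability rule for sparse or
    unseparable regions are provided, together with a synthetic tissue-image
    simulator with per-cell ground truth and a sag metric for
    hyperpolarization-activated current (Ih) current-clamp sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    stats,
    tiff,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
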
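Package: deepDOM
Title: Molecular Characterization and Microbial Association Networks for
    Deep Groundwater Dissolved Organic Matter
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for ultrahigh-resolution mass spectrometry analysis of
    dissolved organic matter (DOM) in groundwater: multi-sample peak-list
    alignment at ppm tolerance, CHNOSP molecular formula assignment with
    isotopologue verification and contaminant filtering, normalization and
    occurrence filtering, van Krevelen compound classification and
    intensity-weighted molecular indices (AI_mod, MLB_w, elemental ratios),
    Bray-Curtis ordination and distance-based redundancy analysis against
    hydrochemistry, Procrustes congruence testing, a compositional
    proportionality (clr / rho) network linking molecular formulas to
    microbial amplicon sequence variants with permutation-FDR edge
    thresholding, fast-greedy modularity and z/P node roles, radiocarbon
    and stable-isotope arithmetic, and a synthetic-data generator with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    vegan,
    igraph,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
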
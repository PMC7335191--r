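Package: megarates
Title: Morphological Disparity and Evolutionary Rate Series Through Deep Time
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for megaevolutionary analyses of discrete morphological data
    on time-calibrated phylogenies. Implements maximum observable rescaled
    distances (MORD) between taxa scored for discrete characters, principal
    coordinates ordination with the Cailliez correction for negative
    eigenvalues, bootstrapped sum-of-variances disparity in stratigraphic time
    bins, extraction and bipartition-pooling of relative clock rates from dated
    posterior tree samples with segmented LOESS trendlines, an
    assumption-driven pairwise testing procedure (Shapiro-Wilk,
    Fligner-Killeen, transformations, t or Wilcoxon tests), and a synthetic
    data generator (fossilized birth-death trees, lognormal branch-rate
    regimes, Mk-evolved characters, matrix degradation, pseudo-posterior tree
    samples) with recorded ground truth. Reads and writes NEXUS character
    matrices and rate-annotated Newick trees.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
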
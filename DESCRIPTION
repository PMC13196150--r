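Package: VesiQuant
Title: Quantification of Vesicle Trafficking and Membrane Localization in
    Fluorescence Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify intracellular trafficking of membrane
    transporters from fluorescence microscopy: plasma-membrane versus
    cytosol fluorescence from confocal z-stacks (sum projection, Huang
    threshold, iterative erosion masks), vesicle-endosome colocalization
    in two-channel TIRF time series (difference-of-Gaussians spot
    enhancement, Voronoi-Otsu labeling, triangle-threshold reference
    masks, overlap-score classification), intensity-threshold
    percent-volume colocalization, single-particle track linking with a
    stationary/dynamic displacement taxonomy, and line-scan intensity
    profiles. A synthetic-image generator produces TIRF movies, confocal
    membrane-ring cells, and track cohorts with full ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    tiff,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    EBImage,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
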
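Package: poldep
Title: Polarity Protein Dependency Networks from Internally Controlled
    Live-Cell Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify genetic dependency relationships between
    fission yeast cell-polarity proteins from internally controlled
    fluorescence microscopy. Mixed fields of wild-type and deletion cells
    are simulated as two-channel z-stacks (GFP polarity marker plus a red
    spindle-pole-body genotype tag), quantified by maximum projection and
    circular-ROI intensity measurement at both cell tips and the cytosol,
    normalised to co-imaged wild-type controls, and summarised as a
    significance-called dependency matrix. The called matrix is converted
    into a signed directed network whose two-protein and larger feedback
    loops are enumerated and classified.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    igraph,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
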
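Package: contactsv
Title: Control-Free Structural Variant Detection from Hi-C Contact Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects large-scale structural variants (deletions, duplications,
    inversions and translocations) from a single Hi-C contact matrix without a
    matched control sample. Raw counts are converted to distance-stratified
    z-scores, a local-contrast saliency map highlights bin pairs whose
    interaction frequency deviates from their spatial neighbourhood, and
    two-dimensional total-variation segmentation extracts coherent
    above-threshold blocks as candidate rearrangement junctions. Breakpoints
    are polished at a finer bin size via sign changes of the leading principal
    component, and calls are typed from the marginal coverage profile and the
    local junction geometry. The package ships a power-law Hi-C simulator with
    embedded rearrangements, controllable depth and tumour purity, and a
    mismatch-tolerant evaluation harness (precision, recall, F1, PR curves).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    generics,
    Matrix,
    mgcv,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
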
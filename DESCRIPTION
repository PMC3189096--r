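Package: menseg
Title: Meningioma Segmentation from Paired T1/T2 MR Slices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Automatic segmentation of meningioma from co-registered
    non-contrast T1- and T2-weighted brain MR slices. The joint 256x256
    T1/T2 intensity histogram is partitioned by fuzzy c-means, each
    defuzzified group is consolidated by seeded region growing (largest
    connected component seed, mean +/- 2 SD merge rule), tumor-bearing
    groups are selected by knowledge-based rules (bounding box, bilateral
    histogram laterality, solidity, area) and the merged mask is refined
    morphologically. Includes percent-match / correspondence-ratio
    evaluation against a ground-truth mask and a synthetic head phantom
    generator with known tumor masks for end-to-end testing.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    grDevices,
    graphics,
    utils,
    png,
    yaml,
    RNifti
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    pracma
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
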
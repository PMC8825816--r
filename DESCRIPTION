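Package: octcyst
Title: Rule-Based Detection of Cystic Fluid Regions in Retinal OCT B-Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fast, segmentation-free detection of cystic (fluid-filled) regions
    in retinal optical coherence tomography (OCT) B-scans. Candidate cyst
    boundary pixels are found from significant vertical light-to-dark intensity
    transitions and confirmed by counting significant diagonal transitions
    inside flanking rectangular patches. A per-column dark-to-light
    transition-tracking algorithm locates vessel-shadow columns so that
    candidates caused by shadow artifacts can be discarded before an image is
    labelled cystic or non-cystic. Includes a synthetic B-scan phantom
    generator with ground truth, a sensitivity/specificity evaluation and
    parameter-sweep harness, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    tiff,
    yaml,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
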
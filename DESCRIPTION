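Package: vitrehaze
Title: Vitreous Haze Quantification from OCT Volumes and Eye-Level
    Association Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies vitreous haze from raw optical coherence tomography
    (OCT) macular volume scans as the ratio of mean signal intensity above
    the internal limiting membrane (ILM) to mean intensity below it, and
    analyses its eye-level associations with retinal-layer and brain-volume
    covariates. Includes a synthetic OCT phantom and cohort generator with
    known ground truth, an ILM surface detector for raw volumes, ETDRS-grid
    sector averaging for macular layer thickness, quality-control accounting
    and disability stratification, Gaussian generalized estimating equations
    with an exchangeable working correlation and robust sandwich variance
    for two correlated eyes per subject, and a reproducible end-to-end
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tiff,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
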
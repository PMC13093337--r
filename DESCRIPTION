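Package: owhscreen
Title: Multi-Modal Screening Analysis for Organotypic Brain-Slice
    Neuroprotection Studies
Version: 0.1.0
Authors@R:
    person("OWH", "Screen Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for multi-modal neuroprotection screening in
    organotypic whole-hemisphere (OWH) brain-slice cultures subjected to
    oxygen-glucose deprivation (OGD). Provides pyknotic-nucleus quantification
    from DAPI-stained histology (Laplacian-of-Gaussian detection, seeded
    watershed splitting, an eight-feature nucleus descriptor and a random-forest
    pyknosis classifier), microglial shape-mode morphometrics (contour
    registration, PCA and clustering), four-model drug-combination synergy
    evaluation (combination subthresholding, highest single agent, response
    additivity, Bliss independence), Gaussian graphical models with Fisher-Z
    edge selection, targeted-panel differential expression and PCA with
    hypergeometric gene-set enrichment, and cross-validated prediction-interval
    detection of emergent combination-treatment transcriptomic effects. A
    seeded synthetic-data module generates every input with known ground truth
    so the full pipeline is testable without raw study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    png,
    igraph
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
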
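Package: eosid
Title: Identification of Airway Eosinophil Gene Expression After Allergen Challenge
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to attribute bulk airway gene expression to eosinophils by
    combining perturbation-based fold-change filters: genes up-regulated in
    bronchoalveolar lavage (BAL) cells after segmental allergen challenge,
    genes decreased after eosinophil depletion with mepolizumab, and genes
    associated with marker-gated sputum eosinophilia after whole-lung
    allergen challenge, intersected in a three-way Venn. Includes a
    two-compartment cell-mixture simulator with known ground truth for
    benchmarking the selection pipeline, relative quantification of qPCR
    data by the comparative threshold-cycle (2^-ddCt) method with
    standard-curve efficiency estimation, and recovery scoring against
    simulated truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
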
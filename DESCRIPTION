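Package: pleioconj
Title: Conditional and Conjunctional FDR Analysis of Cross-Trait GWAS Pleiotropy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies genetic loci shared between two complex traits from
    GWAS summary statistics alone. Implements stratified (conditional) Q-Q
    and fold-enrichment diagnostics, genomic inflation control, empirical
    conditional false discovery rates (condFDR) and their conjunctional
    combination (conjFDR), shared-locus calling with nearest-gene
    annotation, and a seeded two-trait summary-statistics simulator with
    known pleiotropic structure for calibration and power studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
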
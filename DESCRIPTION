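Package: cfscreen
Title: Simulation and Evaluation of Multi-Tier Neonatal Cystic Fibrosis
    Screening Protocols
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Executable decision engine for tiered neonatal cystic fibrosis
    heel-prick screening strategies (immunoreactive trypsinogen, pancreatitis
    associated protein, CFTR mutation panel, extended gene analysis with a
    failsafe rule), together with a seeded synthetic newborn-cohort simulator
    with ancestry-stratified Hardy-Weinberg genotypes, quantile-calibrated
    log-normal biomarker distributions, screening test-property evaluation
    (sensitivity, specificity, positive predictive value), and an exact
    autosomal-recessive carrier-risk calculator.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
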
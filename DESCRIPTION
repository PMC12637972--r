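Package: cellcompete
Title: Stem-Cell Competition Dynamics Under Chronic Low-Dose-Rate Radiation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Stochastic models of radiation-induced stem-cell competition in a
    fixed-size stem-cell pool. Intact cells are converted irreversibly to
    damaged cells by radiation track hits at a dose-rate parameter lambda,
    while cell division and elimination follow a Moran process in which the
    elimination probability is proportional to a frequency-dependent cost
    given by a 2x2 interaction cost matrix. Provides a well-mixed engine, a
    periodic square-lattice engine with Moore neighborhoods, closed-form
    fixation probabilities and the very-low-dose-rate approximation of the
    mean time for damaged cells to occupy the pool, an exact absorbing-chain
    oracle, pool-size shape classification, dosimetry helpers, and a
    reproducible experiment runner with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
NeedsCompilation: yes
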
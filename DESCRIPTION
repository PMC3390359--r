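Package: gpmcomplexity
Title: Genetic Complexity of Genotype-to-Phenotype Maps via Boolean
    Network Libraries
Version: 0.2.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies the genetic complexity of genotype-to-phenotype
    maps (GPMs) as the normalized surplus of genotypic over phenotypic
    diversity, C = (m^n - p)/(p - 1).  Provides exhaustive synchronous
    Boolean-network genotype libraries (by order, size, and topology
    class) with attractor censuses, topology analytics (in-degree
    distributions, elementary-loop reports, relative-complexity
    prediction), the threshold-network formalism with the packaged
    yeast cell-cycle network, and systematic perturbation scans
    (single-edge deletion and addition, per-node input reassignment).
    Exhaustive censuses are implemented in C++ for speed.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
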
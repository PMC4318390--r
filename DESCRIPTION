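Package: fresco
Title: Mining Frequent Spatially Cohesive Residue Patterns in
    Macromolecular Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Apriori-style frequent-pattern mining over labeled 3D point
    clouds derived from protein (and protein-DNA) structures. Patterns of
    amino-acid and base labels are scored by their support across a
    structure collection and by a cohesive radius, the average
    smallest-enclosing-ball radius of the best-matching residue
    combination per structure. Includes an exact Welzl minimum enclosing
    ball, a branch-and-bound best-match search, a within-structure
    label-permutation significance test with Bonferroni control, and
    downstream association statistics: domain and gene-ontology
    hypergeometric enrichment, optimal-growth-temperature correlation
    screens, and sequence-separation classification of pattern matches. A
    synthetic-structure generator with plantable cohesive motifs and
    covariate effects supports fully reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
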
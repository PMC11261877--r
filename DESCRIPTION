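Package: rrndb
Title: Construction and Analysis of Non-Redundant rRNA Operon Reference
    Databases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds quality-checked reference databases of full-length
    16S-ITS-23S ribosomal RNA operons from annotated genome assemblies.
    Extracts and links rRNA gene features from GFF3 annotations, applies
    partial-gene, spacer-length and contig-boundary filters, dereplicates
    operon sequences by length-sorted greedy centroid clustering into
    representative and consensus databases, and assigns cluster-level
    taxonomy under three systems (representative, lowest common ancestor,
    lowest majority rank). Includes intragenomic diversity analytics,
    IUPAC-aware in-silico PCR evaluation of degenerate primer panels, and
    a deterministic synthetic-genome simulator with planted operons for
    fully reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
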
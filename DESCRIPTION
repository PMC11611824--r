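Package: cabletax
Title: Species- and Genus-Level Delineation of Cable Bacteria from Long
    16S rRNA Gene Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reproducible pipeline for delineating the diversity of
    cable bacteria (filamentous, sulfur-oxidizing Desulfobulbaceae) from
    long (>= 800 bp) 16S rRNA gene sequences.  Implements reference-set
    identity screening, conserved-region and monophyly curation,
    complete-linkage species-level clade clustering at the conventional
    98.7 percent identity cutoff, tree-guided genus-level cluster
    delineation at the 94.5 percent guide value, an in-silico twin of the
    nested PCR and Sanger consensus protocol used to obtain full-length
    16S sequences from single filaments, and per-site biogeographic
    summaries by salinity category.  A synthetic radiation generator with
    planted ground truth makes every stage testable without database
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    phangorn,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
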
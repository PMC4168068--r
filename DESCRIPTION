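Package: phamily
Title: Comparative Genomics of Bacteriophage Cohorts via Protein Phamily
    Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for organizing small cohorts of related bacteriophage
    genomes the way comparative phage genomics is done in practice: all-vs-all
    protein similarity with explicit E-value and percent-identity cutoffs,
    single-linkage clustering of proteins into phamilies ("phams") with orpham
    (singleton) detection, shared-pham and core-genome relationship tables with
    a percentage grouping rule, neighbor-joining phylogeny of large terminase
    proteins with DNA-packaging-strategy inference, whole-genome nucleotide
    identity and dotplots, electron-micrograph morphology summaries, and
    tape-measure-protein based matching of co-isolated phages to their genomes.
    A synthetic cohort generator evolves annotated phage genomes with known
    ortholog-group truth (divergence, gene gain/loss, tandem duplication,
    horizontal block transfer) so every stage of the pipeline is testable
    end-to-end without external data.
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
    igraph,
    jsonlite,
    purrr,
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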
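Package: repeatpop
Title: Reference-Free Repeat Profiling and Population Structure from Skim Sequencing
Version: 0.1.0
Authors@R:
    person("repeatpop", "developers", email = "repeatpop@example.org", role = c("aut", "cre"))
Description: Graph-based clustering of low-coverage whole-genome shotgun reads
    into repeat families, per-individual repeat abundance quantification and
    differential-abundance testing between populations, in silico chromosome
    painting of repeat clusters with cluster-diagnostic k-mers and correlation
    with gene density, and a contrast of population structure inferred from
    repeat-abundance profiles versus SNP genotypes. Includes a synthetic-data
    generator (repeat libraries, annotated genomes, structured populations,
    skim-sequencing reads) so every stage is testable with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    igraph,
    jsonlite,
    Rcpp,
    S4Vectors,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
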
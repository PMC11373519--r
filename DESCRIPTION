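Package: gargkit
Title: Genome Ancestral Recombination Graphs as Tidy Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Data structures and algorithms for ancestral recombination
    graphs (ARGs) represented as genome ARGs (gARGs): directed acyclic
    graphs of haploid genomes whose edges are annotated with the genomic
    intervals over which a child genome inherits from a parent. Provides
    validation of node/edge tables, conversion from the classical
    event-based ARG encoding (common-ancestor and breakpoint-annotated
    recombination nodes), sequential recovery of local genealogical trees
    along the genome, propagation and resolution of ancestral material
    with respect to a sample set, a graded ladder of ARG simplification
    operations, coalescence-span statistics, and small forward-time
    Wright-Fisher and backwards coalescent-with-recombination simulators
    for generating test ARGs. Objects are tibbles throughout, with
    broom-style tidy()/glance() methods and ggplot2 autoplot() support.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    rlang,
    stats,
    tibble
Suggests:
    ape,
    withr,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
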
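Package: polykmer
Title: K-mer Based Partitioning of Allopolyploid Genomes into Subgenomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Partitions chromosome-scale allopolyploid genome assemblies into
    evolutionarily coherent subgenomes using repetitive k-mer content alone.
    Discovers candidate subgenome-enriched canonical k-mers by high-copy and
    fold-enrichment filtering across homoeologous chromosome groups, clusters
    chromosomes by correlation distance on marker densities, validates markers
    with one-way ANOVA and Tukey's honestly-significant-difference test
    (Bonferroni corrected), localizes markers into binned density tracks,
    segments chromosomes by subgenome ancestry with a Viterbi hidden Markov
    model to call homoeologous exchanges, and dates LTR retrotransposon
    insertions from 5'/3' LTR divergence under the Jukes-Cantor model.
    Includes a synthetic allopolyploid simulator with staged hybridizations,
    transposable-element bursts and ground-truth output for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    ape,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    methods,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
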
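Package: subfrac
Title: Subgenome Fractionation and Chromatin-Environment Analysis for
    Paleopolyploid Genomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to study biased fractionation and gene dominance between
    the two subgenomes of a paleotetraploid genome (modelled on maize1 and
    maize2 versus their sorghum outgroup). The package partitions chromosomes
    into arms and pericentromeric regions from gene density, repeat content
    and recombination rate; stratifies homoeologous gene pairs and accessible
    chromatin regions (ACRs) by chromatin environment; estimates Ka, Ks and
    omega by Nei-Gojobori (1986) codon counting and Jukes-Cantor distances
    for non-coding sequence; classifies per-tissue expression dominance with
    the two-fold horse-race rule; computes windowed metagene profiles of
    transposable elements, 24-nt siRNAs, weighted DNA methylation and histone
    ChIP signal; and quantifies ACR retention, accessibility and chromatin
    loop distribution. A fully parameterised synthetic two-subgenome data
    generator makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
biocViews: Epigenetics, Genetics, WholeGenome, Annotation
Config/testthat/edition: 3
RoxygenNote: 7.3.3
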
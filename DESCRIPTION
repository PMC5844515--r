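Package: recombean
Title: Recombination Landscapes and Linkage Disequilibrium in Selfing Crop Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to build recombinant inbred line (RIL) linkage maps from
    biallelic marker genotypes (two-point recombination fractions, LOD
    grouping, marker ordering, Kosambi distances), anchor gene-based markers
    to a physical map from alignment hits, estimate Marey-map recombination
    landscapes with pericentromeric-plateau detection, compute
    genepool-stratified diversity statistics (MAF, PIC, nucleotide
    diversity, folded site-frequency spectra with Wright-Fisher neutral
    expectations) and pairwise linkage disequilibrium (D, D-prime,
    r-squared, Fisher exact tests) with decay-curve fitting, and correlate
    gene density with recombination rate in sliding windows. A seeded
    synthetic-data generator (selfing RIL populations, structured diversity
    panels, synthetic genomes and marker flanking sequences) makes every
    stage testable end-to-end. Modeled on the common bean (Phaseolus
    vulgaris) BAT93 x Jalo EEP558 mapping population and its
    Andean/Mesoamerican diversity panel.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    igraph,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
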
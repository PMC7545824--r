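Package: TetradMap
Title: Mapping-by-Sequencing Identification of Causative Mutations from
    Phenotype-Pooled Tetrad Progeny
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies causative mutations in haploid forward-genetics
    screens (modelled on Chlamydomonas reinhardtii) from whole-genome
    variant calls. Implements the read-frequency triage cascade
    (frequency cutoff, wild-type subtraction, non-synonymous selection,
    cross-experiment intersection), bulked-segregant filtering of
    phenotype-pooled outcross progeny, origin tagging of variants against
    background and outcross SNP panels with clean-flank linkage-region
    sizing, and HGVS-style coding-change annotation in precursor and
    mature-protein coordinates. A companion simulator generates toy
    genomes, UV-style mutagenesis, tetrad meioses with Haldane crossovers,
    backcross and outcross breeding schemes, and pooled-sequencing variant
    tables with coverage and base-call noise, so the whole pipeline is
    testable at desk scale.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Genetics, VariantDetection, Sequencing, Software
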
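Package: savscan
Title: Genomic Features of Exonic Variants that Modulate Splicing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scores exonic single-nucleotide variants for features that
    discriminate splice-affecting variants (SAVs) from splicing-neutral
    polymorphisms: loss, gain and alteration of exonic splicing
    enhancers and silencers (ESE/ESS) across hexamer, octamer and
    position-weight-matrix motif collections; a permutation-based
    neutral expectation for the nine categories of motif change,
    weighted by an empirical base-substitution bias; a regulatory
    constraint (RC) score built from a 192-entry codon-position
    conservation matrix; an ectopic splice-site creation metric (delta
    SS) over sliding 5' and 3' splice-site windows; exon-definition
    features (splice-site strength, exon and intron-flank motif
    densities, six-section variant position, junction occupancy
    profiles); and a stratified bootstrap comparison framework with a
    Shapiro-Wilk normality gate. A deterministic synthetic fixture
    generator emulates every input format at toy scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    BiocGenerics,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
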
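Package: cncc
Title: Genome-Wide DNA Double-Strand Break End Structures by
    Coverage-Normalized Cross Correlation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Determines the end structures (blunt, 3'-overhang,
    5'-overhang) of DNA double-strand breaks genome-wide at
    single-nucleotide resolution from strand-specific break-mapping
    sequencing data. Implements the coverage-normalized cross
    correlation (CNCC) statistic between positive- and negative-strand
    break-end coverage, a stringent two-step shuffled control
    (value permutation plus bounded position wiggle), a site-masking
    sensitivity scan, quantification of end-resection signatures,
    genomic-region break-density annotation (BPMM), detection of
    strand-specific spike pairs for motif-site export, and a
    restriction-digest simulator with ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    BiocGenerics,
    GenomeInfoDb,
    IRanges,
    GenomicRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    GenomicAlignments,
    rtracklayer,
    optparse,
    jsonlite,
    yaml,
    withr
biocViews: Sequencing, Coverage, DNADamage, Epigenetics, Software
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'profile.R'
    'break_io.R'
    'cncc-package.R'
    'cncc_core.R'
    'region_density.R'
    'shuffle_control.R'
    'sensitivity.R'
    'spike_pairs.R'
    'synthetic_breaks.R'
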
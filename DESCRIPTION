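Package: zipperscan
Title: Leucine-Zipper Annotation and Evolutionary Characterization of bZIP
    Transcription-Factor Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the computational characterization of plant basic
    region-leucine zipper (bZIP) transcription-factor families. Detects the
    basic-region motif (N-x7-R/K), assigns coiled-coil heptad registers
    (positions a-g) to leucine zippers, and classifies inter-helical g-e'
    and a-a' residue contacts as attractive, repulsive, or neutral to assess
    homo- versus heterodimerization propensity. Implements the Nei-Gojobori
    (1986) counting method for Ka/Ks estimation with Jukes-Cantor correction
    and protein-guided codon alignment, tandem/segmental duplication
    classification, intron-phase and exon-symmetry profiling from GFF3 gene
    models, promoter cis-regulatory element scanning with IUPAC patterns,
    protein molecular weight and isoelectric-point calculation (EMBOSS pKa
    set), and expression-matrix summarization with complete-linkage
    clustering. A synthetic-data module generates inputs with known ground
    truth for every stage so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
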
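Package: zedsense
Title: H2A.Z 3'-End Occupancy and Antisense Transcription Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An analysis pipeline linking occupancy of the histone variant
    H2A.Z (budding-yeast Htz1) at gene 3' ends to the initiation and
    abundance of antisense transcripts. Implements ratio-based ChIP
    background subtraction, gene-anatomy signal partitioning, metagene
    profiles and occupancy-vector clustering, strand-specific RNA
    normalisation to a fixed sense-strand total, peak-transcript
    association by a downstream/upstream fold rule, contingency and
    randomisation tests for co-localisation, a negative-binomial
    differential-expression stand-in, gene-arrangement typology and
    5'/3'-occupancy pattern classes, together with a synthetic-data
    generator with programmable ground truth so the whole pipeline runs at
    desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    BiocGenerics,
    GenomeInfoDb,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils,
    methods
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
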
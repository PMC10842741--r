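Package: nrdtools
Title: Genomic Analyses of Nuclear RNA Decay Phenotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for the quantitative genomics readouts used to study
    nuclear RNA catabolism in mouse embryonic stem cells. Implements
    transposable-element family enrichment against a shuffled-interval
    background with chromatin-state stratification, full-length versus solo
    LTR (MERVL) structural classification, RNAPII promoter-proximal pausing
    ratios, scale-regions metagene profiles, PROMPT and eRNA classification
    of de novo transcription units, premature poly(A)-site termination
    analysis, gene-length and exon-count expression-asymmetry statistics,
    and preranked gene-set enrichment (ES/NES with a permutation null).
    Ships a seeded synthetic-genome generator with planted ground truth so
    every analysis stage can be exercised end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    data.table,
    jsonlite,
    withr,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    fgsea
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
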
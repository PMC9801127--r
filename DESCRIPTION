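Package: trnamap
Title: Mutational Profiling Analysis of tRNA Modification Enzymes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for functional screening of tRNA modification enzymes by
    reverse-transcription mutational profiling (MaP). The package designs
    single-point substitution variant libraries of annotated tRNAs, builds T7
    transcription cassettes, simulates RT-signature sequencing reads (with
    misincorporation, RT stops, sequencing error, skewed pool abundances and
    3' adapters), quantifies per-position mutation rates by semi-global
    alignment and per-variant modification levels by exact-sequence-match
    counting (the M_rate statistic with untreated-sample background
    subtraction), classifies recognition elements, and provides downstream
    statistics (Michaelis-Menten kinetic fits, linear regression, replicate
    group tests).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    Biostrings,
    minpack.lm,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
biocViews: Sequencing, Transcriptomics, Epitranscriptomics, Software
RoxygenNote: 7.3.3
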
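Package: ribodecouple
Title: Joint Ribosome-Profiling and RNA-Seq Analysis of Transcription-Translation Decoupling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the joint analysis of ribosome-protected-fragment (RPF)
    and total-RNA count data: TMM between-sample normalization, CPM/RPKM
    expression filters, negative-binomial exact differential-expression
    testing with Benjamini-Hochberg correction, global and per-gene
    translation-efficiency statistics, classification of genes into
    transcriptionally driven versus translationally up/down-regulated
    groups, preranked gene-set enrichment and hypergeometric
    over-representation analysis, and quantification of polysome-gradient
    qPCR profiles with spike-in correction. A negative-binomial simulator
    plants known regulatory classes so that every stage of the pipeline can
    be validated against ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    fgsea
Config/testthat/edition: 3
RoxygenNote: 7.3.3
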
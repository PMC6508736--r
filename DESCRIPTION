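Package: sertolisig
Title: Sertoli Cell Signature Transcripts from Bulk Testis RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies Sertoli cell signature transcripts from bulk human
    testis RNA-seq by a two-step screen: a cross-species fold-change filter
    on purified rat testicular cell transcriptomes followed by
    cell-composition subtraction deconvolution of the human testis
    transcriptome against published Leydig and germ cell profiles, with
    three pass/fail specificity criteria. Includes the supporting pipeline
    stages: CPM filtering, TMM normalization, beta-actin ratio comparisons,
    a negative-binomial conditional exact test with Benjamini-Hochberg
    correction, signature-panel median rescaling, k-means and PCA
    exploratory views, donor cohort summaries, and a negative-binomial
    synthetic cohort generator with designated ground-truth signature
    genes for end-to-end recovery testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    edgeR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
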
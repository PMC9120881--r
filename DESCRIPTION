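Package: shallowCNA
Title: Tumour-Fraction and Copy-Number Monitoring from Shallow cfDNA
    Whole-Genome Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Copy-number analysis of low-depth whole-genome sequencing of
    circulating free DNA (cfDNA) for treatment monitoring in hepatocellular
    carcinoma. Implements GC/mappability bias correction and panel-of-normals
    normalization of 1-Mb bin counts, a hidden Markov model over log2 copy
    ratios that segments the genome and estimates tumour fraction by
    expectation-maximization (with a constrained second pass for low
    tumour-fraction samples), chromosome-arm level event calling and
    copy-number burden summaries, tumour-fraction change classification of
    treatment response, and the accompanying outcome statistics (Kaplan-Meier
    with log-rank, Cox regression, ROC with Youden cut-off, association
    tests). A synthetic cohort generator produces bin counts and linked
    clinical/outcome tables with known ground truth so the whole pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    survival,
    pROC,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
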
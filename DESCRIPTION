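Package: chromsig
Title: Disease Classification from 5C Chromatin Conformation Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Classifies disease samples from chromosome conformation capture
    carbon copy (5C) interaction-frequency matrices. Provides readers and
    writers for my5C-style tab-delimited contact matrices and BED fragment
    maps, iterative primer-efficiency and array-scale normalization, a
    soft-margin polynomial-kernel support vector machine trained by
    sequential minimal optimization (with one-vs-one multiclass voting and
    an information-gain decision tree alternative), leave-one-out
    cross-validation with accuracy and Matthews correlation coefficient,
    discriminatory-contact ranking by information gain with MDL supervised
    discretization and two-sample t-test filtering, and a synthetic 5C
    panel simulator with planted class-specific contacts for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    e1071,
    rtracklayer,
    GenomicRanges,
    IRanges,
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
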
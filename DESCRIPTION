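Package: ailqtl
Title: QTL Mapping by Selective DNA Pooling in Advanced Intercross Lines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for high-resolution quantitative trait locus (QTL) mapping
    by selective DNA pooling (bulk segregant analysis) in advanced intercross
    line (AIL) populations. Implements LOESS smoothing of pooled allele
    frequencies along chromosomes and of among-replicate standard deviations by
    allele frequency, single-marker association tests based on tail-versus-
    control allele-frequency differences with empirical replicate-based
    standard errors, estimation of the number of true null markers with
    adaptive false discovery rate thresholding, 1-log-drop QTL support
    intervals with adjacent-peak splitting, and allele substitution effect
    estimation from truncation-selection theory. A forward simulator of
    two-parent AIL experiments (recombination, drift, two-stage selection,
    pooling, sequencing noise) supports calibration and parameter-recovery
    testing of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    vcfR,
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
VignetteBuilder: knitr
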
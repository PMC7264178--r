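Package: epirescue
Title: Rescue Quantification for Double-Mutant Transcriptomes and
    Spike-In H3K4me3 ChIP-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying mutual suppression (genetic rescue) in
    factorial four-genotype designs that combine a chromatin writer mutant,
    an eraser mutant, and their double mutant. Provides a negative-binomial
    Wald test for differential expression from count matrices with
    median-of-ratios size factors, spike-in nucleosome quality control and
    normalization for differential H3K4me3 region calling, rescue statistics
    (direction cross-classification, paired signed-rank shift tests,
    regression-slope tests against unity, threshold-based rescue-driver
    calling), mRNA-by-chromatin quadrant integration with Fisher gene-set
    enrichment, and a synthetic-data generator that plants known genotype
    effects so that every stage of the pipeline can be validated against a
    ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    DESeq2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
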
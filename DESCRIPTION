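Package: xquant
Title: Quantification of X-Chromosome Territory Compaction, Radial
    Position, and Derepression in C. elegans Dosage Compensation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Single-nucleus quantification of chromosome-territory
    compaction and radial nuclear position from multi-channel 3D image
    stacks (rolling-ball background subtraction, Otsu segmentation, 3D
    volume fraction, three-zone equal-area radial assay, line-scan
    enrichment, normalized mean intensity), the X-versus-autosome
    derepression statistic on differential-expression tables with its
    Wilcoxon rank-sum significance, contingency-based viability
    statistics, and a synthetic-data generator (nucleus image stacks,
    negative-binomial count matrices, progeny survival tables) with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    stats,
    tiff,
    tools,
    utils
Suggests:
    DESeq2,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
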
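Package: aneuploidr
Title: Simulation and Analysis of Gene Expression Dosage Effects in Aneuploids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying genomic imbalance in aneuploids: a synthetic
    aneuploid transcriptome simulator with known per-gene dosage-response
    classes (dosage effect, dosage compensation, inverse and direct trans
    effects), the cis/trans expression-ratio distribution pipeline used for
    maize chromosome-arm dosage series (replicate averaging, low-expression
    filtering, 0.05-width ratio binning, per-partition medians),
    distribution-comparison statistics (two-sample Kolmogorov-Smirnov,
    Bartlett's test, a Welch-t differential-expression caller with
    Benjamini-Hochberg adjustment), and the genome-normalized transcriptome
    size estimator that compares droplet digital PCR mRNA/gDNA ratios with
    RNA-seq relative expression.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
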
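Package: ascna
Title: Allele-Specific Copy-Number Alteration Inference from Single-Cell RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects allele-specific somatic copy-number alterations (copy loss,
    copy gain, copy-neutral loss of heterozygosity, and a whole-genome-duplication
    warning) per gene per cell from single-cell RNA-seq count data. A read-depth
    module fits a negative-binomial mixture over absolute copy states, and a
    B-allele-frequency module fits a beta-binomial mixture over allelic-bias
    states on locally (EM) and globally (dynamic-programming) phased gene-bin
    counts. State posteriors are smoothed across cells with a KNN graph and along
    the genome with a forward-backward HMM, then combined into four final CNA
    states. Includes a haplotype-aware count-level CNA simulator with ground-truth
    masks and a ROC/ARI benchmarking harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    mclust,
    dplyr,
    tibble,
    tidyr,
    rlang,
    readr,
    ggplot2,
    generics,
    yaml,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    MASS,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
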
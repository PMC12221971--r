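Package: methylfate
Title: Gamete DMR Calling, Imprint Fate Tracking and Methylome Segmentation
    on Bisulfite CpG Calls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for whole-genome bisulfite CpG methylation analysis in
    early development: reading, destranding, pooling and filtering
    per-cytosine call tables; tile-based differential methylation between
    gametes with an exact count test and FDR control; tracking of gamete
    DMRs through embryonic stages and adult tissues to classify transient,
    lineage-restricted and life-long (candidate imprinted) regions with
    nearest-gene annotation; change-point segmentation of methylomes and
    detection of partially methylated domains; and chromosome-level
    analyses (embryo sexing from X/pseudo-Y read counts, X-versus-autosome
    and allele-specific methylation, expression-linked gene-body
    methylation, X/A expression ratios). Includes a synthetic-methylome
    generator with a planted-feature truth ledger so that every stage of
    the pipeline can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    mclust,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
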
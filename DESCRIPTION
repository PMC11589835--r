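Package: pwaskit
Title: Proteome-Wide Association Studies from Tissue Proteomes and GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for tissue-based proteome-wide association
    studies (PWAS). Trains cis-genetic elastic-net prediction models of protein
    abundance from a genotyped tissue panel, applies the summary-statistics
    Z-score association test to GWAS results, performs approximate conditional
    analysis against known risk variants using linkage-disequilibrium reference
    data, and reports FDR-controlled protein-trait associations together with
    protein-RNA correlation and PWAS/TWAS comparisons. A synthetic-data module
    with known ground truth makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    limma,
    purrr,
    readr,
    rlang,
    stats,
    tibble
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
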
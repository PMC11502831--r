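Package: gibnet
Title: Genetically Informed Brain Networks from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Multivariate genetic-architecture analysis of regional brain
    phenotypes from GWAS summary statistics. Estimates SNP heritabilities,
    genetic covariances and their block-jackknife sampling covariance by LD
    score regression; discovers latent factors ("genetically informed brain
    networks") with an odd/even-chromosome exploratory-then-confirmatory
    factor analysis fitted by diagonally weighted least squares with sandwich
    standard errors; runs a multivariate GWAS of each latent factor with
    genomic-inflation diagnostics and distance-based locus clumping; tests
    spatial overlap of factor-defined region sets against reference
    parcellations with a permutation Dice statistic and FDR correction; and
    ships a synthetic summary-statistics generator with a planted factor
    structure so every stage is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
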
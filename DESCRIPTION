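Package: gsemr
Title: Genomic Structural Equation Modelling and Mendelian Randomization
    for GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Multivariate analysis of genome-wide association study (GWAS)
    summary statistics: quality control and allele harmonization, LD score
    regression for SNP heritabilities and genetic covariances with block
    jackknife sampling covariances, genomic factor analysis (PCA/Kaiser
    scree, exploratory factor analysis, confirmatory and structural models
    fit by diagonally weighted least squares with sandwich standard
    errors), latent-factor GWAS with the Q_SNP heterogeneity statistic,
    and bidirectional two-sample Mendelian randomization with five
    estimators and heterogeneity, pleiotropy and directionality
    diagnostics. Includes a synthetic multi-trait summary-statistics
    generator with a known latent genetic architecture so every stage can
    be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    pracma,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
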
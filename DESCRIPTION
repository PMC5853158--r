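Package: atopymr
Title: Two-Sample Mendelian Randomisation of Atopy-Related Traits on Glioma Risk
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools and a reproducible analysis workflow for two-sample Mendelian
    randomisation (MR) of atopy-related traits (atopic dermatitis, asthma and hay
    fever, serum IgE level, self-reported allergy) on glioma risk using published
    per-SNP summary statistics. Implements summary-statistic parsing and allele
    harmonisation, LD pruning, five causal estimators (inverse-variance weighting,
    bivariate-normal maximum likelihood, weighted median, mode-based estimate and
    MR-Egger regression), pleiotropy and heterogeneity diagnostics (HEIDI-outlier
    screening, Cochran's Q and I-squared), the per-doubling odds-ratio conversion
    for binary exposures, a binary-exposure/binary-outcome case-control GWAS
    simulation harness, and a priori power and instrument-strength calculations.
    The instrument sets ship as plain-text fixtures and every reported estimate is
    recomputed from them at run time.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    ggplot2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor,
    pracma
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
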
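Package: pleioscan
Title: Two-Cohort Proteome-Wide Association Analysis of Statin Use and
    Inflammation Proteins
Version: 0.1.0
Authors@R:
    person("pleioscan", "maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for proteome-wide association analysis of
    statin intake against Olink inflammation-panel proteins (NPX scale) in a
    discovery/replication two-cohort design. Implements panel-level quality
    control (limit-of-detection exclusion rules, duplicate-assay resolution,
    LOD substitution), an iterative standard-deviation-ratio outlier detector,
    baseline-characteristics tables (median/IQR, Wilcoxon rank-sum, Pearson
    chi-square), multivariable linear models with restricted-cubic-spline
    linearity checks, Cook's distance influence filtering and regression
    diagnostics, median (quantile tau = 0.5) regression sensitivity fits,
    Benjamini-Hochberg false-discovery-rate adjustment, E-value quantification
    of unmeasured confounding, and cross-cohort replication classification.
    Ships a synthetic two-cohort generator that emulates the statistical
    structure of the target studies so the full pipeline is testable without
    restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
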
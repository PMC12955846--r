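Package: morelimpute
Title: Two-Stage Imputation of Sporadic and Systematic Missing Values in
    DNA Methylation Beta-Value Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Imputes missing values in DNA methylation beta-value matrices
    (rows = CpG probes, columns = samples). Sporadically missing values are
    filled with a suite of standard imputers (trend statistics, moving
    windows, nearest neighbours, expectation-maximization, Buck's method,
    matrix completion, chained regression, random forests). Systematic
    missingness arising from array incompatibility - probes absent from every
    sample run on one array generation - is handled by multi-output
    regression and learning (MOREL): samples are split into two groups from
    their probe presence/absence patterns, and direction-specific
    multi-output models (random forest, linear support vector regression,
    nearest neighbours, or a single-hidden-layer neural network) predict one
    group's beta values from the other's, trained on CpGs observed in both
    groups. Includes evaluation metrics (MAE, RAE, RMSE, R-squared),
    beta-tier stratification, differential-CpG selection,
    principal-component concordance, and a synthetic benchmark generator
    with configurable structural and sporadic missingness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ranger,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
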
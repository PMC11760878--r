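Package: mrmediate
Title: Two-Sample Mendelian Randomization with Two-Step Mediation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization (MR) from GWAS
    summary statistics: reading and harmonizing summary tables, instrument
    selection and quality control (genome-wide significance, distance/LD
    clumping, F-statistic filtering, confounder and outcome-association
    exclusion), five MR estimators (inverse-variance weighted, MR-Egger,
    weighted median, simple and weighted mode), sensitivity diagnostics
    (Cochran's Q, Egger intercept, MR-PRESSO outlier detection, Steiger
    directionality, sample-overlap bias), and two-step mediation analysis
    via the product-of-coefficients (Sobel) method with a two-stage least
    squares first stage.  A synthetic GWAS generator with configurable
    pleiotropy and sample overlap supports calibration and recovery
    experiments, and a pipeline orchestrates the full workflow with audit
    logging.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
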
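Package: auxmi
Title: Multiple Imputation with Incomplete Auxiliary Variables
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how missing data in auxiliary variables
    affects estimates obtained from multiple imputation. Provides a
    trivariate-normal synthetic data generator with deterministic
    CDF-cutoff missingness mechanisms for the outcome and the auxiliary,
    a fully conditional specification (chained equations) imputation
    engine with proper Bayesian normal-linear draws and flexible
    polynomial/interaction term specifications, Rubin's rules pooling
    with the fraction of missing information, and a simulation-study
    orchestrator producing bias, empirical standard error and Monte
    Carlo error summaries together with plots of bias relative to
    complete records analysis.
License: MIT
Encoding: UTF-8
Imports:
    MASS,
    stats,
    utils,
    tools,
    parallel,
    yaml,
    jsonlite,
    ggplot2,
    patchwork
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
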
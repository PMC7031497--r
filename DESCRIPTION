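Package: itvcv
Title: Low-Bias Estimation of Intraspecific Trait Variation via the
    Coefficient of Variation
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying intraspecific trait variation (ITV) with
    the coefficient of variation (CV) while controlling small-sample bias.
    Provides eight CV estimators (the naive plug-in estimator, the
    normal-theory correction, skewness- and kurtosis-aware corrections in
    the style of Breunig and Bao, and four simple composites), three data
    normalizations (natural log with an add-one shift rule, cube root, and
    min-max), a contaminated-gamma simulator of trait pools with extreme
    large values, a with-replacement resampling engine that measures
    estimator bias across sample sizes, and a search for the minimum sample
    size achieving a stated accuracy band. A command-line interface exposes
    the simulate/estimate/evaluate/minsize workflow for long-format
    species-trait tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
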
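Package: ineqshift
Title: Socio-Economic Health Inequality Indices Under Composition Change
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes summary measures of socio-economic health inequality
    (the slope index of inequality, the relative index of inequality and the
    population attributable fraction) together with pairwise rate
    differentials, for event rates stratified over ordered socio-economic
    groups such as educational levels. Provides a simulator of hypothetical
    educational-level distributions at fixed mortality rates, extraction and
    characterisation of index-versus-share curve families, a decomposition of
    index changes between scenarios into a mortality-differential component
    and a composition-shift component, and a synthetic stratified-population
    generator with Poisson death counts for confidence-interval work.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
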
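Package: pagap
Title: Gap Analysis of Protected-Area Representativeness for Plant Gamma Diversity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to assess how representative a protected-area network is of
    regional plant species richness (gamma diversity) from vegetation-plot
    data. Classifies survey plots inside or outside protected polygons by
    buffer overlap, partitions species into exclusive and shared sets,
    estimates richness per analysis unit with the Chao2 incidence estimator
    (plus Michaelis-Menten and asymptotic-regression robustness checks and
    sample-based rarefaction), fits and contrasts species-area relationships
    inside versus outside the network with AICc model selection and bootstrap
    confidence intervals, flags units deviating from the network-wide mean
    with deviation-coded binomial GLMs, and validates comparisons on
    propensity-matched plot subsets. Includes a synthetic-data generator that
    emulates the structure of continental vegetation-plot archives and
    protected-area layers, with ground truth for recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
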
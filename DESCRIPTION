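Package: spsdose
Title: Stochastic Parametric Skeletal Dosimetry for Bone-Seeking Beta Emitters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic parametric skeletal dosimetry (SPSD) toolkit for active
    bone-marrow dose factors of incorporated 89Sr and 90Sr(+90Y). Generates
    stylized voxel phantoms of hematopoietic bone segments (stylized solids,
    cortical shells, rod-like trabecular lattices), samples individual
    variability of macro- and micro-architecture with correlated truncated
    distributions, evaluates analytic dose-factor surrogates for trabecular and
    cortical bone sources, and propagates inherent (unshared) and introduced
    (shared) uncertainty components up to skeletal-average dose factors,
    including a two-dimensional Monte Carlo for population dose realizations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
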
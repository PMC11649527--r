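Package: winauth
Title: Wine PDO Authentication from Elemental Profiles by SIMCA and Cascaded PLS-DA
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Chemometric authentication of wines carrying Protected Designation
    of Origin (PDO) labels from multi-element concentration profiles, such as
    those measured by energy-dispersive X-ray fluorescence after evaporative
    pre-concentration. Implements NIPALS principal component analysis, SIMCA
    class modelling with DModX distance-to-model limits, Hotelling T2 score
    limits, NIPALS PLS2 discriminant analysis, Ward hierarchical clustering,
    LOQ-aware variable screening with pairwise Student t-tests, and a
    consecutive country-region-PDO classification cascade with two-category
    rescue models, sample elimination, score-outlier exclusion and
    single-element threshold overrides.  Validation follows the control-lab
    protocol: leave-one-out sensitivity, non-member specificity and accuracy.
    Ships a synthetic censored elemental-profile generator emulating the
    nested class structure of a multi-country PDO survey so the whole
    pipeline is testable without proprietary data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    jsonlite
Config/testthat/edition: 3
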
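Package: pollentree
Title: Gain-Ratio Decision Trees and Feature Selection for Pollen Grain Morphometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Selects the morphological features of pollen grains that best
    discriminate birch (Betula), hazel (Corylus) and alder (Alnus) at the
    genus level. Implements C4.5-style (J4.8) gain-ratio decision-tree
    induction with fractional instance weighting for missing values,
    stratified repeated five-fold cross-validation, split-attribute-based
    feature selection with low-cost subset augmentation, and paired subset
    comparison. Includes a calibrated synthetic morphometry generator that
    emulates the 13-feature, 3-taxon study design, and CSV/ARFF input and
    output for feature tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    foreign,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
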
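Package: ecoscape
Title: Ecosystem Service Valuation, Fuzzy Ecological Quality and Land Cover Change Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "maintainer@example.org")
Description: Tools for quantifying the ecological impact of land use/land
    cover (LULC) change between two dates. Implements benefit-transfer
    ecosystem-service valuation with coefficient-sensitivity (elasticity)
    analysis, a fuzzy-overlay ecological-quality (EQ) index built from
    seven fuzzified parameter layers combined with the GAMMA operator,
    Markovian transition-matrix change detection with alluvial flow
    tables, and confusion-matrix accuracy assessment (overall accuracy,
    Cohen's kappa). A synthetic neutral-landscape generator produces
    paired before/after categorical rasters with known transition
    structure and class-correlated covariates so the full pipeline is
    testable without satellite data. Rasters are read and written as
    ESRI ASCII grids.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, tools, jsonlite, yaml
Suggests: testthat (>= 3.0.0), withr, e1071, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
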
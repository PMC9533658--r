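Package: ipci
Title: Index of Plant Community Integrity for Prairie Pothole Wetlands
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for probability-based condition assessment of prairie
    pothole wetlands from zoned quadrat vegetation surveys. Implements the
    nine-metric Index of Plant Community Integrity (IPCI) with ordinal
    0/4/7/11 metric scoring and condition categories for temporarily and
    seasonally ponded wetlands, floristic quality assessment from
    coefficients of conservatism, spatially balanced site selection by
    generalized random tessellation stratified (GRTS) sampling with
    primary/alternate designation and replacement, quadrat layout plans,
    unweighted condition summaries, and a synthetic-data generator that
    emulates plant communities along a disturbance gradient for testing
    the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
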
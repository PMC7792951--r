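Package: ltcineq
Title: Socioeconomic Inequality and Horizontal Inequity in Long-Term Care Use
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for measuring socioeconomic inequality and horizontal
    inequity in the utilization of formal and informal long-term care from
    respondent-level survey microdata. Implements weighted fractional ranks,
    the concentration index and its corrected version for binary outcomes,
    concentration curves, logistic utilization models with robust (sandwich)
    standard errors, indirect need-standardization and horizontal inequity
    indices, a multi-country synthetic microdata generator with a known
    data-generating process, and a study pipeline that produces per-country
    inequality and inequity tables.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    sandwich,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
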
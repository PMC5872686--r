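Package: helioepi
Title: Sun Exposure, Vitamin D and Matched Case-Control Association Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for epidemiological studies of ambient ultraviolet radiation
    (UVR), serum 25-hydroxyvitamin D (25OHD) and disease risk in matched
    case-control designs. Reconstructs cumulative lifetime and recent ambient
    UVR dose from residence histories, time-outdoors behaviour and a monthly
    latitude-by-month climatology; deseasonalizes serum 25OHD by regression
    residuals or a control-based seasonal polynomial; fits unconditional and
    matched-set conditional logistic regression by maximum likelihood with
    Wald odds-ratio inference; produces descriptive case-control comparison
    tables; and simulates matched case-control cohorts with configurable
    race/ethnicity-specific UVR and vitamin D effects for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
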
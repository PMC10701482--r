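Package: qcstability
Title: Stability Assessment of Internal Quality Control Materials by Total
    Change Limits
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for assessing how long internal quality control (QC)
    materials remain stable while stored on an automated clinical chemistry
    analyzer. Builds daily percent-change series (Xt%) against a baseline
    triplicate, derives Total Change Limit (TCL) thresholds that combine
    analytical imprecision (CVa) and within-subject biological variation
    (CVb), classifies imprecision against Fraser performance tiers, and
    applies an exceedance-run decision rule yielding a per-analyte
    loss-of-stability day and maximum permissible storage time. Ships a
    synthetic QC-series generator with configurable degradation drift for
    operating-characteristic studies, plus a transcribed 48-analyte
    reference stability study so the full analysis is reproducible offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
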
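Package: ventrisk
Title: Rapid IUCN Red List Assessment for Species of Insular Habitat Patches
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for rapid, reproducible IUCN Red List extinction-risk
    assessment of species endemic to small, insular habitat patches such as
    deep-sea hydrothermal vent fields. Clusters occurrence records into
    threat-defined IUCN locations using a geodesic distance threshold within
    management areas, computes area of occupancy (AOO) on the standard
    2 x 2 km grid and extent of occurrence (EOO) as a minimum convex polygon
    in a local equal-area projection, maps seabed-mining regulatory regimes
    onto continuing decline and plausible future threat, evaluates criteria
    B1, B2 and D2, and assigns a Red List category with a canonical criteria
    string. Includes regulatory-change scenario analysis, a location-threat
    matrix generator, a synthetic ridge-system occurrence generator with
    constructive ground truth, curated case-study fixtures, and a command
    line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    withr
Config/testthat/edition: 3
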
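Package: wardplan
Title: Regional Hospital Ward Planning with Contribution Margins and
    Exact Location-Allocation Optimisation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Economic planning of paediatric and obstetric hospital wards in
    low-density regions. Implements a DRG (diagnosis related group)
    contribution-margin ladder with step-fixed staffing and bed costs, an
    exact mixed-integer location-allocation optimiser over which wards to
    open and how cases are allocated, break-even case-volume search,
    classical bed-demand (Hill-Burton) and hexagonal-catchment cost
    formulas, travel-time catchment and accessibility analysis, and a
    synthetic region generator so the whole pipeline is testable without
    external geodata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
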
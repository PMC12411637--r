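Package: noduledose
Title: Occupational Radiation Dose Assessment for Deep-Sea Polymetallic Nodules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates occupational effective doses from the naturally
    occurring radioactivity (NORM) of deep-sea polymetallic nodules along the
    transport and pyrometallurgical processing chain. Implements the external
    gamma pathway via geometry-dependent ambient dose equivalent rates
    H*(10), internal exposure from inhalation of radioactive dust using
    ICRP inhalation dose coefficients (AMAD 5 um), and a physical radon
    model: diffusive exhalation from an extended thick source, comminution
    release, and the indoor steady-state/transient ventilation balance.
    Nuclide vectors are propagated through the smelting flowsheet
    (mass-ratio enrichment into the third-reduction slag, volatilisation of
    Pb-210 and Po-210 into flue dust). Scenarios compose pathways into
    annual dose reports with regulatory classification against the 1 and
    20 mSv/a benchmarks, and a Monte Carlo layer propagates measurement
    uncertainties of the specific activities to dose distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    withr
Config/testthat/edition: 3
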
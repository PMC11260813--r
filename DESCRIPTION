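Package: et0calib
Title: Reference Evapotranspiration Models with Hydrological-Year Selection
    and Bayesian Coefficient Calibration
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computes daily reference crop evapotranspiration (ET0) from
    station weather records by five models (FAO-56 Penman-Monteith,
    Priestley-Taylor, Hargreaves, McCloud, FAO-24 Radiation), selects
    typical hydrological years by Pearson Type III frequency analysis of
    annual precipitation, recalibrates the FAO-24 Radiation coefficients
    against Penman-Monteith standard values by an iterative conjugate
    posterior-mean scheme, and evaluates agreement at daily, dekad and
    monthly scales with R2, RMSE, MAE and Willmott's index. Includes a
    seeded synthetic weather generator for a temperate continental
    monsoon station so the whole pipeline is testable without external
    data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
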
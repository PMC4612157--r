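Package: saltcanopy
Title: Functional-Structural Canopy Simulation for Dissecting Salinity
    Effects on Tomato Dry Mass Production
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A dynamic functional-structural plant model (FSPM) of a tomato
    canopy under combined salinity and temperature stress. Grows a 3D
    virtual canopy (16 plants, phytomers, seven-leaflet rhombus leaves,
    144 degree phyllotaxis), traces daily light interception with a Monte
    Carlo path tracer over a discretised sky dome, converts absorbed light
    to dry mass through a light-use-efficiency function, estimates the
    interval-wise relative canopy light-use efficiency from allometric
    relationships between leaf area and shoot mass, dissects salinity's
    effect on shoot dry mass into architectural and non-architectural
    components, and scans the sensitivity of dry mass production to
    architectural traits. Includes a synthetic-data generator emulating the
    greenhouse evaluation experiment for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
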
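Package: canopyAGB
Title: Individual-Tree Aboveground Biomass from Airborne and Terrestrial
    Laser Scanning
Version: 0.1.0
Authors@R:
    person("Forest", "Informatics Lab", email = "dev@example.org",
           role = c("aut", "cre"))
Description: Tools to estimate individual-tree aboveground biomass (AGB)
    from tree height and crown radius extracted from airborne (ALS) and
    terrestrial (TLS) laser scanning point clouds.  Provides a synthetic
    forest and point-cloud simulator (conifer and broadleaf plots with
    calibrated height-diameter-crown coupling), progressive TIN ground
    filtering, DEM/CHM construction, marker-controlled watershed crown
    segmentation, least-squares circle fitting of stem slices for DBH,
    optimal-assignment fusion of ALS and TLS tree lists, species
    allometry for reference AGB, and nine candidate height/crown-radius
    allometric model forms fitted and scored (R-squared, RMSE, rRMSE)
    over seven species-mixture scenarios with a 70/30 train/test split.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    interp,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    readxl
Config/testthat/edition: 3
RoxygenNote: 7.3.3
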
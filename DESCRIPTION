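Package: fvcdyn
Title: Spatiotemporal Analysis of Fractional Vegetation Cover Dynamics
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing long-term fractional vegetation cover (FVC)
    dynamics from annual vegetation-index rasters: dimidiate-pixel FVC
    inversion from NDVI with percentile endmembers, per-pixel Theil-Sen slope
    and Mann-Kendall trend testing with five-class trend grading,
    rescaled-range (R/S) Hurst persistence and combined future-trend
    classification, coefficient-of-variation stability grading, pixelwise
    partial correlation of vegetation with temperature and precipitation,
    aggregation to square analysis units with global Moran's I scale
    selection, the GeoDetector family of spatial stratified-heterogeneity
    statistics (factor, interaction, risk and ecological detectors with
    optimal discretization), raster product comparison metrics (MAE, RMSE,
    R2, SSIM, PSNR), and seeded synthetic-data generators with known ground
    truth for validating every step.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
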
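Package: vigapfill
Title: Gap-Free Daily Vegetation-Index Reconstruction from Contaminated
    Satellite Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reconstructs gap-free daily vegetation-index (NDVI) grids from
    cloud-contaminated daily satellite records. Valid observations are
    identified with a three-month sliding-window percent-bias screen plus an
    interannual month-level screen; gaps and invalid data are filled by
    segmented quartic-polynomial fitting split at the annual greenness peak,
    with residual gaps filled from the adjacent four years. Includes
    per-pixel validation metrics (r, R2, MAE, RMSE, percent bias), quality
    classification, monthly maximum-value compositing, nearest-neighbour
    regridding, NetCDF-4 input/output on regular latitude/longitude grids,
    and a synthetic contaminated-scene generator with a contamination ledger
    for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ncdf4,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
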
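Package: polsarvol
Title: Stand-Level Forest Growing Stock Volume Retrieval from
    Quad-Polarimetric SAR Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Retrieves stand-level growing stock volume (GSV, m3/ha) of
    planted forest from time series quad-polarimetric SAR. Implements the
    Yamaguchi four-component decomposition of the 3x3 coherency matrix,
    fused polarimetric characteristics (Dbl/Odd, Vol/Odd, Dbl x Vol,
    Dbl x Vol/Odd), temporal averaging of acquisitions, an exponential
    general linear model with a log link and a semi-exponential
    (water-cloud type) saturation model as retrieval functions, and a
    leave-one-out cross-validation assessment protocol (Pearson screening,
    RMSE, relative RMSE, R squared, exceedance flagging). A seeded
    synthetic-scene generator emulates plot inventories, log-linear
    power-GSV relations with acquisition-level disturbance, and multilook
    speckle, so the whole pipeline is testable without satellite data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
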
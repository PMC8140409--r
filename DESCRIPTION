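Package: pm25hia
Title: Gridded Health Impact Assessment of Fine Particulate Matter
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates premature mortality attributable to long-term ambient
    PM2.5 exposure on regular latitude-longitude grids. Implements the
    non-linear GEMM and IER exposure-response families with confidence-interval
    propagation, per-cell attributable-mortality computation by cause of death
    and 5-year age group with region-specific baseline mortality rates,
    conservative population regridding, national population projection to a
    future scenario, present-versus-future scenario differencing with a
    climate/population decomposition, and a synthetic-data generator that
    emulates the statistical structure of the gridded inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ncdf4,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
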
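Package: driftgrid
Title: Survey Statistics for Floating Marine Debris
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying the spatial heterogeneity of floating
    plastic debris from ship-based surveys: concentration normalization for
    surface net tows, classical and robust (Cressie-Hawkins) empirical
    semivariograms with linear or Gaussian model fits, line-transect distance
    sampling with binned perpendicular distances (detection-function fitting,
    AIC selection, effective strip widths and group correction factors),
    Monte Carlo power analysis for detecting multiplicative changes in
    right-skewed concentration data with the Mann-Whitney U test, sampling
    adequacy simulation for exponential concentration marginals, combined
    micro/macro debris size-frequency spectra with ocean-coverage estimates,
    and plastic-to-plankton removal arithmetic. A synthetic-data module
    generates tow, particle, sighting and transect-segment tables with the
    statistical structure the analyses assume, so the full pipeline runs
    end-to-end without access to cruise data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    geosphere,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
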
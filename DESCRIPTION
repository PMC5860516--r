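Package: dhrpanel
Title: Two-Stage Modelling of Seasonal and Spatiotemporal Variation in
    Health-Outcome Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for a two-stage analysis of seasonally varying,
    spatially indexed health time series such as monthly prescribing
    rates.  Stage one fits a dynamic harmonic regression (a Gaussian
    state-space model in which the coefficients of the seasonal sine and
    cosine terms evolve as random walks) to the area-wide series by
    Kalman filtering and maximum likelihood, with lagged temperature as
    a driver and a static harmonic regression as the comparator.  Stage
    two fits a random-intercept linear mixed model to the unit-level
    panel with the stage-one fitted curve as an offset, by profiled
    REML/ML, and returns BLUPs with prediction intervals.  Diagnostics
    include the residual autocorrelation function, empirical variograms
    with permutation envelopes after trend-surface detrending, and the
    spatiotemporal (distance by time-lag) variogram.  A synthetic panel
    generator with drifting seasonality, a shared temperature driver,
    practice random intercepts and optional spatially or
    spatiotemporally correlated residuals supports simulation studies
    and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    lme4
Config/testthat/edition: 3
RoxygenNote: 7.3.3
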
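Package: fitexex
Title: Growth Kinetics, Spectra and Cross-Correlation Analysis of Plant
    Elongation Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative analysis of elongation growth in
    plant organs (maize coleoptile segments in particular). Fits the
    linear-plus-Gompertz "fitexex" growth law u(t) = A*t + B +
    C*exp(-exp(-D*(t - t_e))) to relative-elongation time series and
    derives kinetic quantities (diffusion rate k2, time constant T2, a
    turgor-pressure proxy) from the Lockhart/Ortega cell-expansion
    framework; interconverts growth-rate and elongation records and
    summarises rate peaks; computes detrended power spectra of growth
    rate and reads off the Lorentzian zero-frequency intensity; computes
    discrete pH x elongation cross-correlations, their lag derivative and
    the zero-lag derivative-jump estimate of H+ activity per micrometre;
    and aggregates the empirical E_H+ constant linking membrane potential
    to the pH x elongation product. A seeded synthetic-data generator
    reproduces the statistical structure every stage assumes, so the
    whole pipeline is testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
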
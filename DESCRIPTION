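Package: vischange
Title: Simulation and Analysis of a Visual Change-Detection Task in Mice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how mice detect sustained changes in the speed
    of a noisy drifting grating. Provides a generative simulator of the task
    (lognormal temporal-frequency noise, block-structured change times, a
    configurable lick agent, and synthetic fluorescence), descriptive
    behavioral statistics (psychometric and chronometric curves, discrete
    hazard rates, lick-triggered averages, stratified data splits), a sparse
    variational Gaussian-process model of the momentary lick hazard with
    learned stimulus filters, automatic relevance determination, warped-time
    and hierarchical block kernels, and the imaging-side analyses used to
    relate stimulus fluctuations to mesoscale calcium signals: channel-ratio
    hemodynamic correction, lagged and interaction regressions,
    multiexponential latency fitting, blocked cross-validated ridge
    deconvolution, and asymmetric Student-t neuropil correction for
    two-photon traces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    signal,
    zoo,
    minpack.lm,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
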
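Package: tggpp
Title: Robustness and Uncertainty Analysis of the Temperature-and-Greenness GPP Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating the robustness of the temperature-and-greenness
    (TG) light-use-efficiency model of terrestrial gross primary production
    (GPP) at monthly flux-site scale. Provides the TG forward model with
    profiled proportionality scalar, quality screening and singular spectrum
    analysis smoothing of satellite greenness and temperature series, Morris
    elementary-effects parameter screening, Bayesian calibration of the three
    temperature parameters by random-walk Metropolis-Hastings with convergence
    and prior-dominance diagnostics, normalized Taylor-diagram skill
    statistics, Johnson relative-weight attribution of GPP variance to
    greenness and climate drivers, and a seeded generator of synthetic
    multi-year flux-site data with known ground truth for all twelve plant
    functional types.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
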
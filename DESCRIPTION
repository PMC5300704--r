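Package: flagrowth
Title: Injection-Diffusion Modelling of Bacterial Flagellar Growth
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Stochastic modelling and analysis of length-dependent bacterial
    flagellar growth.  Implements an injection-diffusion model of flagellin
    export: monomers are loaded at the filament base at a fixed attempt rate
    with a force-assisted entry rule, undergo single-file Brownian motion in
    the narrow filament channel, and crystallize at the growing tip.
    Includes helical 2D-projection length correction, instantaneous
    growth-rate curve construction with median filtering, grid-search
    fitting of the diffusion coefficient and loading strength to
    growth-rate-vs-length data, secretion-energetics estimates, and a
    seeded synthetic-data generator emulating the published measurement
    design.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    withr,
    stats,
    graphics,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
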
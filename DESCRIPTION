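Package: patchfr
Title: Functional Responses and Predator-Prey Coexistence Across Patch
    Sizes and Refuge Availabilities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates allometric predator-prey feeding trials on a
    gridded arena with prey refuges using an individual-based model,
    fits Real's (type II/III) functional response with habitat-dependent
    half-saturation density and Hill exponent by negative-binomial
    maximum likelihood with BIC model selection, and propagates the
    fitted interaction into an allometric Rosenzweig-MacArthur
    predator-prey model with patch-scaled extinction boundaries to map
    coexistence over patch size and refuge availability.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    grDevices,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
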
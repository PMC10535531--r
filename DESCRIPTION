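Package: cyanospec
Title: Spectral Band Requirements for Cyanobacteria Detection in Inland Waters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for deriving minimal spectral band
    configurations for cyanobacterial pigment retrieval from hyperspectral
    imagery of inland waters. Generates labeled synthetic reflectance spectra
    (water-leaving, top-of-atmosphere, and bottom-of-Rayleigh) over seven
    optical water types with mixed cyanobacteria-algae populations, resamples
    them through a configurable overlapping-band imager model, trains
    multilayer-perceptron retrievals of chlorophyll-a, phycocyanin and the
    cyanobacteria:algae ratio, attributes per-channel importance by feature
    permutation, and reduces attribution profiles to nine-band and three-band
    configurations together with their merged minimum-viable and optimal
    syntheses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
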
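Package: nirsdcs
Title: Simulation and Performance Characterization of Hybrid Time-Domain
    NIRS and Diffuse Correlation Spectroscopy Instruments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward photon-migration models (time-domain diffuse reflectance,
    semi-infinite and two-layer correlation diffusion), a multi-tau software
    correlator for photon time tags, inverse fitting of time-of-flight
    histograms and intensity autocorrelations, the BIP, MEDPHOT and nEUROPt
    performance-assessment statistics, DCS noise characterization, and
    photon-level synthetic instrument generators with end-to-end occlusion and
    pulsatility analysis pipelines.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
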
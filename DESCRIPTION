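Package: neurotact
Title: Neuromorphic Tactile Encoding with Spiking Afferents and Nociceptors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of a bio-inspired tactile encoding
    system: a 5x5 pressure-sensor array is innervated by a population of
    digital afferents (slowly adapting SA-I, rapidly adapting RA-I) and
    nociceptors modeled with discretized Izhikevich dynamics, including a
    Q13.18 fixed-point arithmetic mode mirroring digital-hardware
    implementations. Provides a synthetic-stimulus generator for trapezoidal
    indentation of cone- and cube-shaped objects, random weighted
    receptive-field construction, rate-coding (windowed spike counts with
    PCA) and temporal-coding (Victor-Purpura spike-train distance) decoders,
    k-nearest-neighbor classification with cross-validation, and fault
    injection experiments for taxels and afferent channels.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    class,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
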
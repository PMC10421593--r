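Package: cavprime
Title: Voltage-Sensor Priming of Presynaptic Calcium Channels and
    Somato-Axonal Coupling Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Forward simulation and inverse fitting of a four-voltage-sensor
    kinetic model of presynaptic voltage-gated calcium (Cav) channels, in
    which subthreshold depolarizations "prime" closed channels and augment
    the calcium current evoked by a following action potential.  Includes
    construction of action-potential and EPSP voltage-command waveforms,
    parameter sweeps, analysis of paired somatic/axonal current-clamp
    recordings (EPSP detection, coupling ratio, cross-correlation lag,
    exponential length-constant fits, cell-attached spike metrics), and
    seeded synthetic-data generators with ground truth for closed-loop
    recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
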
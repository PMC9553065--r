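Package: monpool
Title: Reconstruction of Complete Motoneuron Pool Activity from Identified
    Motor-Unit Spike Trains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reconstructs the recruitment and firing behaviour of a complete
    pool of motoneurons from a small sample of experimentally identified
    motor-unit spike trains (for example from decomposed high-density surface
    EMG) recorded together with a whole-muscle force trace during trapezoidal
    isometric contractions.  The four-step workflow maps the identified units
    onto a size-principle-ordered pool via a muscle-specific recruitment
    threshold distribution, estimates the common synaptic current input from
    the cumulative spike train, calibrates the size parameter of leaky
    integrate-and-fire motoneuron models against smoothed discharge rates,
    and simulates the full pool to predict the effective neural drive to the
    muscle.  A multi-motor-unit Hill-type muscle stage converts the simulated
    spike trains into isometric force.  Synthetic fixture generators emulate
    the statistical structure of the source datasets so that every stage is
    testable without the original recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    jsonlite,
    minpack.lm,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
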
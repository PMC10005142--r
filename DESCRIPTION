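Package: spiq
Title: Direct-Injection Single-Particle ICP-MS Data Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated evaluation of time-resolved single-particle ICP-MS
    acquisitions from direct-injection (sample loop) introduction. Separates
    the ionic background from discrete nanoparticle events by iterative
    piecewise mean-plus-k-sigma thresholding, fits ionic response
    calibrations per matrix, determines matrix-matched transport
    efficiencies from counted reference nanoparticles, converts events to
    spherical-equivalent particle sizes and number/ionic/total
    concentrations, and assembles time-resolved dissolution series. A
    Poisson transient-signal simulator with known ground truth supports
    validation of every stage without instrument data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
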
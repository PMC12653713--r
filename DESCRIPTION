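Package: tonguecast
Title: Color-Cast Simulation and Correction for Tongue Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating and removing global color casts in clinical
    tongue photographs. Provides a paired-image cast simulator (brightness and
    single-channel casts), four classical white-balance and chart-based
    correctors (gray world, perfect reflection, standard-deviation-weighted
    gray world, and polynomial chart regression), a 26-layer convolutional
    encoder-decoder regression network for learned correction together with a
    5-layer baseline network, a CIELAB/PSNR/SSIM evaluation suite with
    cast-severity classification, and a bootstrap plus paired t-test model
    comparison protocol. A built-in synthetic tongue-image generator makes the
    whole pipeline testable without any photographic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    jpeg,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
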
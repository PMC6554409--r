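Package: nremdyn
Title: Excitable Population Dynamics of NREM Sleep
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing UP/DOWN state dynamics of adapting
    recurrent neural populations during NREM sleep. Implements a
    Wilson-Cowan-type rate model with slow spike-frequency adaptation and
    its inhibition-stabilized (E-I) extension, including fixed-point and
    regime analysis, Ornstein-Uhlenbeck noise-driven simulation, sticky
    threshold UP/DOWN state detection with a Hartigan dip bimodality gate,
    Kolmogorov-Smirnov product matching of dwell-time distributions, LFP
    slow-wave and sharp wave-ripple event detectors, and a ground-truthed
    synthetic recording generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    deSolve,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
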
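Package: mlsel
Title: Multilevel Selection Dynamics of Cooperators and Cheaters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic simulator and analytic toolkit for a two-level
    (individual and group) selection model of cooperation. Groups composed of
    social (cooperator) and asocial (cheater) individuals reproduce by
    consuming within-group resources, split on reaching a size threshold, and
    die under neutral, relative or absolute group-fitness regimes. The package
    provides the exact per-step stochastic dynamics, closed-form and numeric
    survival theory (splitting-probability recursions, harmonic-number
    proliferation thresholds, Moran-limit fixation probabilities),
    replicate-ensemble drivers for phase portraits and trajectory panels, and
    an off-lattice agent-based biofilm model in which extracellular-matrix
    production plays the role of the social trait.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
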
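Package: synmotif
Title: Synergy Screening of Inhibitor Pairs on Signaling Motifs via an
    Extended Bliss Independence Criterion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing drug-combination synergy on kinetic models of
    signaling reaction networks. Michaelis-Menten activation/deactivation
    motifs (serial cascades, parallel convergent branches, negative feedback)
    are represented as data-driven ODE systems, inhibitors as multiplicative
    parameter perturbations, and combination effects via the Bliss
    independence criterion: the Synergism Assessment Factor S compares the
    combined survival ratio with the product of single-inhibitor survival
    ratios, and its mixed partial derivative DS gives a sensitivity-based
    sufficient condition for synergy over a dose rectangle. Structure-based
    simplification rules clamp intermediate products so that the sign of DS
    on a reduced subsystem predicts the sign on the full network, and a
    comparison-principle check verifies when a feedback loop preserves the
    combination effect. Includes dose-grid scanning, a JSON model format,
    seeded random-motif fixtures, and plotting of S surfaces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
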
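Package: fractoc
Title: Liquid TOC Quantification and Size Fractionation of Micro- and
    Nanoplastic Suspensions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying micro- and nanoplastic and nanocellulose
    suspensions by liquid total organic carbon (TOC) measurement and for
    assessing size-based fractionation by centrifugation, filtration and
    asymmetric flow field-flow fractionation (AF4). Implements Stokes-law
    sedimentation with radial g-force gradients in swing-bucket rotors,
    effective and nominal centrifugal size cutoffs, sequential fractionation
    of polydisperse mixtures, TC-TIC data reduction with replicate acceptance
    rules, Poisson particle-injection statistics, carbon mass-balance and
    recovery arithmetic with propagated uncertainties, and a seeded synthetic
    measurement generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
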
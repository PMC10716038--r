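Package: ternabind
Title: Equilibrium Models and Cycle Statistics for Ternary
    Adaptor-Integrin Binding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the quantitative analysis of ternary
    talin-integrin-kindlin complex formation at integrin beta-tails:
    coupled mass-action equilibrium models with tail conformers and a
    direct adaptor-adaptor contact, the energy-square microscopic
    reversibility test on measured dissociation constants with
    first-order and Monte Carlo error propagation, binding-isotherm
    fitting for thermophoresis titrations (one-site, global, signed
    two-component) and fixed-asymptote dose-response displacement
    curves, NMR titration observables (chemical shift perturbations
    with a robust 2-sigma significance threshold, intensity-ratio
    profiles, secondary carbon chemical shifts), and forward
    generators that simulate all of these measurements with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
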
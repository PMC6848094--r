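Package: hepflux
Title: Steady-State 13C Isotopomer and Hyperpolarized Pyruvate Flux Analysis for Perfused Liver
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of hepatic pyruvate metabolism from 13C NMR
    data. Implements a steady-state 13C isotopomer model of the liver TCA
    network that predicts glutamate and lactate multiplet patterns from
    relative fluxes, a nonlinear least-squares engine recovering pyruvate
    dehydrogenase, pyruvate carboxylase and pyruvate-cycling fluxes from
    measured multiplet areas, absolute-flux scaling from hepatic oxygen
    consumption, a simulator and quantifier for hyperpolarized
    [1-13C]pyruvate dynamic spectra, and a synthetic cohort generator for
    validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    Matrix,
    pracma,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
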
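Package: quenchkin
Title: Chlorophyll-Fluorescence Kinetics: PSII Connectivity, Quenching and
    Photoprotection Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantitative analysis of chlorophyll-fluorescence
    kinetics in photosystem II (PSII) antenna research. Implements the
    connected-units (Joliot) sigmoidal fluorescence-induction model for
    DCMU-treated leaves (connectivity J, functional antenna size 1/t_2/3,
    relative optical cross-sections by equal-complementary-area time
    rescaling), a finite plastoquinone-pool model for untreated induction
    rises, saturating-pulse (PAM) quenching analysis (NPQ, qE/qI
    decomposition, quantum-yield partitioning Phi_II/Phi_NPQ/Phi_NO, qL,
    NPQ definite integrals and sigmoidal NPQ-vs-antenna-content fits),
    first-order xanthophyll-cycle de-epoxidation kinetics, exponential
    photoinhibition (Fv/Fm decay) half-time fitting, and hyperbolic
    light-saturation fits for electrochromic-shift (proton motive force)
    curves. Ships genotype presets for PSII antenna mutants and a seeded
    synthetic-trace generator so every analysis is verifiable by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    minpack.lm,
    deSolve,
    Matrix,
    pracma
Suggests: testthat (>= 3.0.0), knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
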
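Package: galnacpbpk
Title: Whole-Body PBPK-PD Modelling of GalNAc-Conjugated siRNAs
Version: 0.1.0
Authors@R:
    person("PBPK", "Maintainers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A whole-body physiologically based pharmacokinetic-pharmacodynamic
    (WB-PBPK-PD) simulator for GalNAc-conjugated small interfering RNAs in the
    mouse. Extravasation follows the two-pore formalism with an additional
    liver-specific permeability pathway; hepatic disposition is driven by
    asialoglycoprotein-receptor (ASGPR) target-mediated drug disposition with
    endosomal trafficking, cytoplasmic escape and RNA-induced silencing complex
    (RISC) formation; mRNA silencing and protein knockdown follow indirect
    response turnover models. Includes a bundled mouse physiology, a compound
    parameter library, a stiff Rosenbrock ODE core, exposure metrics (AUC,
    terminal half-life, AFE/AAFE fold errors), local sensitivity analysis with
    WHO-style classification, bounded least-squares parameter estimation, and a
    synthetic observation generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
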
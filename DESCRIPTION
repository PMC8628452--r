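Package: efluxpc
Title: Transcriptome-Constrained Metabolic Flux Prediction with a Fitted
    Proportionality Constant
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates gene-expression data into genome-scale constraint-based
    metabolic models. Expression values are max-normalized, scaled by a global
    proportionality constant (PC), mapped onto reactions through their
    gene-protein-reaction (GPR) rules (OR = sum of isozyme levels, AND = minimum
    over complex subunits) and imposed as flux bounds, extending the E-Flux
    scheme. The PC is calibrated against a measured growth rate by scanning and
    bisecting the growth-versus-PC curve, and the calibrated flux polytope is
    explored with an artificial-centering hit-and-run (ACHR) sampler to predict
    intracellular and secretion fluxes with mean and standard deviation.
    Includes SBML and COBRA-style JSON model readers, a generator of small
    solvable fixture models with synthetic expression profiles, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
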
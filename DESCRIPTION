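Package: hepatolip
Title: Kinetic Simulation of Hepatocyte Cholesterol and Lipoprotein Metabolism
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A 21-state kinetic model of in vitro hepatocellular cholesterol
    and lipoprotein metabolism: SREBP-2 driven transcription of HMGCR, LDLR
    and PCSK9, receptor-mediated endocytosis of LDL and VLDL,
    PCSK9-mediated LDL-receptor degradation, and three lipid-lowering
    therapy mechanisms (statins, anti-PCSK9 antibodies, small-molecule
    PCSK9 inhibitors). Provides both the dimensional and the
    non-dimensionalised form of the system with an exact mapping between
    them, a stiff-capable Rosenbrock integrator with dosing events,
    steady-state location with Jacobian stability analysis, scenario
    presets for in silico dosing experiments, dose sweeps, and local
    sensitivity analysis.
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
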
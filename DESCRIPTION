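Package: fluxvar
Title: Sources and Components of Flux Variability in Constraint-Based
    Metabolic Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Constraint-based analysis of metabolic flexibility. Loads
    genome-scale metabolic models (BiGG-style JSON or SBML Level 3 with
    the FBC extension), applies medium specifications, and solves the
    linear programs of flux balance analysis (FBA), flux variability
    analysis (FVA) and linear minimization of metabolic adjustment
    (MoMA) on a deterministic bounded-variable simplex backend. On top
    of these it implements the Delta and Sigma flux-variability
    measures, the decomposition of total variability into internal,
    external and growth components, uptake-rate and growth-bound
    condition scans, the two-stage carbon-nitrogen uptake coordination
    procedure, and MoMA-based counting of large flux changes during
    adaptations. Deterministic toy networks with a brute-force
    polytope oracle support verification at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    Matrix,
    jsonlite,
    yaml,
    xml2,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
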
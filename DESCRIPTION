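Package: acylselect
Title: Geometric Reactivity and Acyl-Chain-Length Selectivity Analysis for
    DHHC Acyltransferase Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Post-processing of molecular-dynamics trajectories of membrane
    DHHC acyltransferases in complex with acyl-CoA substrates. Computes
    cavity-fitness (ceiling offset D1), nucleophilic-attack reactivity
    (nucleophile-carbonyl distance D2 and Buergi-Dunitz angle), reactive-state
    classification and in-silico selectivity profiles across acyl chain
    lengths, protein-ligand contact maps, hydrogen-bond and pi-cation
    lifetimes, and membrane-normal partial density profiles. Includes a seeded
    synthetic-trajectory generator with an exact ground-truth ledger so every
    stage is testable without running molecular dynamics.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
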
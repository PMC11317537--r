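Package: kinetmoe
Title: Multitask Mixture-of-Experts Prediction of Enzyme Kinetic Parameters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Joint prediction of the enzyme turnover number (kcat) and the
    Michaelis constant (Km) from enzyme sequence, substrate structure and
    assay conditions with a gated mixture-of-experts multitask regression
    model (customized gate control, CGC). Includes a curation pipeline for
    BRENDA/SABIO-RK style kinetic exports (unit normalization, structural
    and value filters, mutation application, SMILES canonicalization,
    duplicate aggregation), radial-basis-function encoding of pH and
    temperature, pluggable enzyme and substrate embedders with
    deterministic hash-based defaults, stratified splitting, standard
    regression metrics plus hit-ratio evaluation for enzyme engineering,
    and a seeded synthetic-data generator so every stage is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
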
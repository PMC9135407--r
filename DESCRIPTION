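Package: hscTriage
Title: Compound Triage for a Hepatic Stellate Cell Inactivation Screen
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reusable analysis pipeline for a phenotypic high-throughput
    screen that searches for small molecules inactivating hepatic stellate
    cell (HSC) myofibroblasts, read out as lipid-droplet (Bodipy)
    re-accumulation. Implements plate-level scoring with toxicity and
    reproducibility penalties, control-anchored 'Scaled' normalization and
    two-rule hit calling; compound consolidation by standardized canonical
    SMILES with sphere-exclusion Tanimoto clustering, representative
    selection and PAINS/frequent-hitter/formula-duplicate triage; a
    multiplexed delta-Ct qPCR secondary screen fit by ordinary least
    squares with Benjamini-Hochberg FDR and explicit advancement criteria;
    four-parameter logistic dose-response fitting with toxicity-based
    point exclusion and a Priority 1-5 curve rubric; non-compartmental
    pharmacokinetics and microsomal intrinsic-clearance calculations; and
    a synthetic-data generator that emulates every input so the whole
    cascade is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    ChemmineOB,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
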
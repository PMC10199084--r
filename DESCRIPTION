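Package: coxtriage
Title: Hit Triage for COX-2 Inhibitor Virtual Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Staged triage of docking-based virtual screening hits, built around
    the workflow used to nominate andrographolide analogs as cyclooxygenase-2
    inhibitors. Implements ligand-efficiency metrics (inhibition constant,
    ligand efficiency, lipophilic ligand efficiency, fit quality, LELP) with
    threshold classification, Lipinski and Pfizer (3/75) drug-likeness rule
    engines with data-driven ADMET range screening, derivations over quantum
    mechanical output tables (HOMO-LUMO gap, adduct stabilization energy,
    energy-based ranking), molecular dynamics trajectory summary statistics
    (Kabsch superposition RMSD, per-atom RMSF, radius of gyration, geometric
    hydrogen-bond counts, time-series summaries), a configurable screening
    funnel with an elimination ledger and consensus ranking, and a seeded
    synthetic-data generator so every stage is testable without external
    simulation engines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    jsonlite
Config/testthat/edition: 3
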
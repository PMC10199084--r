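# coxtriage

Staged hit triage for docking-based virtual screening campaigns, built
around the workflow that nominates andrographolide (AGP) analogs as
inhibitors of cyclooxygenase-2 (COX-2), the inducible prostaglandin
synthase targeted by anti-inflammatory drugs. The package is for
computational chemists and bioinformaticians who already have engine
outputs — docking scores, ADMET descriptor tables, quantum-chemistry
energy tables, MD trajectories or scalar series — and need the downstream
arithmetic and decision logic to be reproducible and tested.

## What it computes

**Ligand-efficiency metrics** with threshold classification, for binding
energy ΔG (kcal/mol), heavy-atom count HA and lipophilicity logP:

    Ki       = exp(ΔG / RT)                      (molar; RT at 298.15 K by default)
    LE       = −ΔG / HA                          (≥ 0.3 kcal/mol/HA to pass)
    LLE      = −log10(Ki) − logP                 (≥ 3)
    LE_Scale = 0.873 e^(−0.026·HA) − 0.064
    FQ       = LE / LE_Scale                     (≥ 0.8)
    LELP     = logP / LE                         (within [−10, 10])

**Drug-likeness rule engines**: the Lipinski rule of five (fails at ≥ 2
violations of MW ≤ 500, logP ≤ 5, HBA ≤ 10, HBD ≤ 5) and the Pfizer 3/75
rule (rejects logP > 3 with TPSA < 75 Å²), plus data-driven range
screening of arbitrary ADMET fields against a small range grammar.

**QM-table derivations**: HOMO–LUMO gaps, adduct stabilization energies
Δ = E(adduct) − [E(compound) + E(peptide)], consistency flags for
internally contradictory rows, and tie-aware energy rankings.

**MD summary statistics**: optimal-superposition (Kabsch) RMSD, per-atom
RMSF, radius of gyration, geometric hydrogen-bond counts
(0.35 nm / 30° by default), XVG/CSV series ingestion and
mean ± sd summaries with an equilibration skip.

**A screening funnel** — strict energy cutoff, rule stage, metric stage —
with a per-stage elimination ledger and consensus (mean-rank) ordering of
the survivors, and **seeded synthetic-data generators** so every stage is
testable without any engine run.

The printed tables of the reference AGP/COX-2 screen ship as fixtures
(`load_fixture("table1")`, `"table3"`, `"table4"`, `"table5"`).

## Worked example

Run the reference screen through the funnel:

```r
library(coxtriage)

scores   <- load_fixture("table1")   # docking energies, kcal/mol
profiles <- table3_profiles()        # descriptors from the ADMET table

res <- run_funnel(scores, profiles)
res
#> Screening ledger:
#>            stage entering surviving eliminated
#> 1 docking_cutoff       10         8          2
#> 2          rules        8         6          2
#> 3        metrics        6         6          0
#>
#> Final survivors: A1, A2, A3, A4, A6, A7
```

The cutoff stage (strict < −8.00 kcal/mol) eliminates aspirin
(−5.61 kcal/mol) and the parent compound AGP (−7.95); the rule stage then
removes rofecoxib and A5, both rejected by the Pfizer 3/75 rule; the
surviving six analogs clear every efficiency threshold. Individual
metrics, with Ki derived from the binding energy:

```r
rep <- evaluate_metrics(merge(scores[c("compound_id", "binding_energy")],
                              profiles, by = "compound_id"))
rep[rep$compound_id %in% c("A1", "A3", "A5", "Aspirin"),
    c("compound_id", "ki_uM", "le", "lle", "fq", "lelp", "pass_all")]
#> # A tibble: 4 × 7
#>   compound_id  ki_uM    le   lle    fq  lelp pass_all
#>   <chr>        <dbl> <dbl> <dbl> <dbl> <dbl> <lgl>
#> 1 A1           0.140 0.390  4.09 0.965  7.09 TRUE
#> 2 A3           0.531 0.357  3.51 0.883  7.75 TRUE
#> 3 A5           0.810 0.308  2.86 0.835 10.5  FALSE
#> 4 Aspirin     77.2   0.432  2.88 0.773  2.87 FALSE
```

A5 fails on lipophilicity (LLE below 3, LELP above 10) despite adequate
size-normalised potency; aspirin binds too weakly for its lipophilicity
(LLE 2.88) and sits below the fit-quality floor. The tight agreement of
`ki_uM`, `le`, `lle`, `fq` and `lelp` with the published metric table is
asserted by the test suite at its stated tolerances.

For trajectory work, `generate_trajectory()` produces seeded synthetic
trajectories, and `rmsd_series()`, `rmsf_per_atom()`,
`radius_of_gyration()`, `count_hbonds()` and `series_summary()` compute
the standard observables; see the methods vignette
(`vignettes/hit-triage-methods.Rmd`) for the models, conventions and
their rationale.

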
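---
title: "Methods: staged hit triage for docking-based virtual screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: staged hit triage for docking-based virtual screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coxtriage)
```

## The problem

Structure-based virtual screens produce long tables of docking scores that
must be whittled down to a handful of chemically sensible hits. `coxtriage`
implements the downstream half of such a campaign — the part that starts
once docking, ADMET predictors, quantum-chemistry packages and MD engines
have produced their tables — as a reproducible, testable pipeline. Its
reference use case is the triage of andrographolide (AGP) analogs against
the inducible cyclooxygenase isoform COX-2, where 237 docked analogs were
reduced to 7 hits and finally one nominee; the printed tables of that screen
ship as fixtures (`load_fixture()`), so every stage can be exercised against
real numbers without re-running any engine.

The package deliberately does **not** dock, run DFT, predict ADMET
properties or integrate equations of motion. Those quantities are inputs.
What it owns is the arithmetic and decision logic applied to them.

## Ligand-efficiency metrics

For a compound with docking binding energy $\Delta G$ (kcal/mol), heavy-atom
count $N_{\mathrm{HA}}$ and lipophilicity $\log P$:

$$K_i = e^{\Delta G / RT}, \qquad
  \mathrm{LE} = -\frac{\Delta G}{N_{\mathrm{HA}}}, \qquad
  \mathrm{LLE} = -\log_{10} K_i - \log P,$$

$$\mathrm{LE_{Scale}} = 0.873\, e^{-0.026\, N_{\mathrm{HA}}} - 0.064, \qquad
  \mathrm{FQ} = \frac{\mathrm{LE}}{\mathrm{LE_{Scale}}}, \qquad
  \mathrm{LELP} = \frac{\log P}{\mathrm{LE}}.$$

A hit must satisfy LE $\ge 0.3$ kcal/mol/HA, LLE $\ge 3$, FQ $\ge 0.8$ and
LELP within $[-10, 10]$. Three design choices matter here:

* **Temperature.** $RT$ defaults to $1.98720425\times10^{-3} \times 298.15$
  kcal/mol. Published Ki tables rarely state the temperature used, and the
  fixture table back-solves to a slightly smaller $RT$; Ki comparisons
  against such tables should therefore use a ~5% relative tolerance, which
  is how the acceptance suite treats them. Both $R$ and $T$ are
  configurable through `thermo_config()`.
* **Inclusive thresholds.** A compound exactly at a threshold passes. The
  convention is stated in the documentation and reproduces the reference
  pass/fail partition (the failing set is exactly A5 and the two control
  drugs).
* **Ki provenance.** When a measured or previously printed Ki is available
  it can be supplied as `ki_override` and feeds LLE; otherwise Ki comes
  from the binding energy. The provenance is recorded per row in
  `ki_source`. This makes printed LLE columns exactly reproducible instead
  of inheriting the Ki temperature ambiguity.

All internal arithmetic is full precision; rounding is display-only. One
consequence is worth knowing: published metric tables are often computed
*from their own rounded intermediates*. In the reference table the LELP
column is consistent with dividing logP by the 3-decimal LE column (and that
LE column itself mixes rounding with truncation), so a full-precision
recomputation can sit just outside a ±0.01 window of the printed LELP for
individual rows. The package does not imitate rounded-intermediate
arithmetic; the test suite documents the resulting row-level deviation
rather than hiding it.

## Drug-likeness rules and range screening

`lipinski_rule()` counts violations of MW ≤ 500 Da, logP ≤ 5, H-bond
acceptors ≤ 10 and donors ≤ 5, accepting below two violations.
`pfizer_rule()` encodes the 3/75 rule: the *rejection* region is
logP > 3 **and** TPSA < 75 Å². The printed predicate in such tables is
direction-ambiguous ("logP > 3, TPSA < 75"); the polarity used here is fixed
by the Rejected cells of the fixture (rofecoxib and A5, both high-logP,
low-TPSA), and both inequalities are strict.

ADMET fields beyond those two rules are screened by `range_screen()` against
a small declarative grammar (`">x"`, `">=x"`, `"<x"`, `"<=x"`, `"a~b"`,
ascending 3-band scales `band:b0;b1;b2;b3` labelled
excellent/medium/poor, and descending `band_desc:t1;t2` labelled
high/moderate/low). Band fields are Accepted only in their first band. The
shipped ranges come pre-populated from the fixture's permissible-range
column; whether band-scored fields are probabilities or model scores is not
stated by the upstream predictor, so they are treated as opaque values
screened against the printed bands.

## QM-derived quantities

The quantum-mechanics module performs derivations only; all energies are
ingested. `homo_lumo_gap()` returns LUMO − HOMO (eV); smaller gaps mean
higher chemical reactivity. `adduct_stabilization()` implements the
component difference

$$\Delta = E_{\mathrm{adduct}} - \left[E_{\mathrm{compound}} +
E_{\mathrm{peptide}}\right]$$

over electrostatic potential energies. Printed tables of this quantity
conventionally report a *negative* binding energy although the literal
difference over the printed component columns comes out positive; rather
than guess which sign is an erratum, the result carries both `delta` (the
literal difference) and `stabilization` $= -|\Delta|$ (the table
convention), and comparisons use magnitudes. `hlg_consistency()` exists
because ingested tables do contain internally inconsistent rows — the
fixture's peptide row tabulates a gap of 3.33 eV against orbital energies
implying 4.66 eV, and one analog row's binding-energy cell is off by
0.55 kcal/mol from its own component columns. Both are flagged, reported
as computed, and left unreconciled.

## MD summary statistics

`kabsch_superpose()` computes the minimum mass-weighted RMSD over proper
rotations and translations by SVD of the weighted cross-covariance, with
reflection correction (det +1 always). Collinear geometries, where the
rotation about the line is not identifiable, fall back to a flagged
translation-only fit. The implementation is validated against an
independent quaternion characteristic-polynomial oracle to 1e−9 and against
`bio3d`'s fit on random instances.

`rmsf_per_atom()` removes global motion with one round of superposition:
align all frames to the first, form the unweighted mean structure, re-align
the original frames onto that mean, then take per-atom root-mean-square
displacements about the mean aligned position. One round (rather than
iterating to convergence) is deterministic and testable; for the
equilibrated, well-overlapped trajectories this summarises, further rounds
change nothing detectable. Note that superposition absorbs six degrees of
freedom, so for an $N$-atom frame with isotropic per-coordinate jitter
$\sigma$ the expected RMSF is $\sigma\sqrt{3}\sqrt{1 - 2/N}$, slightly below
the naive $\sigma\sqrt{3}$; the property tests use $N$ large enough that
this bias sits inside their tolerance.

`radius_of_gyration()` is the mass-weighted spread about the centre of
mass. `count_hbonds()` applies the common geometric criterion
(donor–acceptor ≤ 0.35 nm, H–D–A angle ≤ 30°, both configurable through
`hbond_criterion()`); each donor–acceptor pair counts once no matter how
many hydrogens qualify. Published MD tables rarely state their criterion,
which is why it is explicit and configurable here.

`series_summary()` uses the *population* standard deviation, matching the
"mean ± sd" convention of trajectory summary tables where the sample/
population distinction is negligible at thousands of frames; the choice is
documented rather than silent. Solvent-accessible surface quantities are
never recomputed from coordinates — a SASA algorithm is a separate project —
but ingested as series (`parse_xvg()`, CSV) and summarised.

## The screening funnel

`run_funnel()` executes, in order: a strict binding-energy cutoff
(default < −8.00 kcal/mol; "lesser than" is read literally, so −8.00
exactly is eliminated and −8.10 survives), the required drug-likeness
rules, and the metric thresholds. Every stage records entrants, survivors
and per-compound elimination reasons in a ledger whose conservation
(entering = surviving + eliminated, stages chained) is enforced by tests.

Final survivors are ordered by `consensus_rank()`: per-criterion tie-aware
ranks (ties share the mean rank), aggregated by mean rank (Borda-like) or
weighted mean rank, with deterministic lexicographic tie-breaking on the
compound id. The reference study's final nomination integrated MD, EPE and
MM/GBSA evidence narratively, without a stated weighting; the package
therefore treats published orderings as fixtures for *single-criterion*
rankings only and asserts nothing about multi-criterion nominations. The
default configuration ranks by binding energy alone.

## The synthetic-data generator

`generate_library()` emulates a docking screen at the reference study's
conditions: 237 compounds by default, Gaussian binding energies centred at
−7 kcal/mol with sd 1 (spanning roughly −5.9 to −8.8, the printed range of
the real screen), heavy-atom counts uniform on 13–38 (the fixture
compounds' sizes up to the declared HA ceiling), Gaussian logP (mean 2.5,
sd 0.8, the fixture's neighbourhood), TPSA uniform on 80–140 Å² so the bulk
sits clear of the Pfizer region, and a configurable fraction of compounds
planted inside it (logP 3.2–4.5, TPSA 40–70). A planted hit receives a
binding energy a stated margin below the library minimum plus
rule-passing descriptors, so pipeline recovery of it is a property, not an
accident. `generate_trajectory()` draws a reference structure once and adds
optional rigid motion plus i.i.d. Gaussian jitter;
`generate_adduct_energies()` draws component energies and an additive
stabilization term that `adduct_stabilization()` recovers exactly.

Generators are pure functions of their spec: one root seed, with
stage-specific streams derived from it, and the caller's RNG state is
restored afterwards. What the generator does *not* emulate: real chemistry
(valence, synthesizability, correlated descriptors beyond the planted
structure), force-field dynamics, or heavy-tailed docking-score
distributions. Passing the property suites therefore demonstrates that the
*pipeline logic* is correct under its stated statistical assumptions, not
that any particular real compound would survive a real screen.

## Problem sizes and numerical choices

The test and acceptance workloads use desk-scale sizes chosen to make the
statistical checks sharp without being wasteful: 100 random instances for
the superposition oracle, 2000-frame trajectories of 30–100 atoms for
fluctuation expectations, 100 seeded 60–100-compound libraries for ledger
and monotonicity properties, 100 replicates for planted-hit recovery, and a
5000-compound library for the Normal-tail survivor fraction (expected
15.87% below −8 for mean −7, sd 1; asserted within three binomial standard
errors). Degenerate inputs are contracts, not crashes: zero heavy atoms,
non-positive Ki, zero LE, atom-count mismatches, single-frame RMSF and
empty post-equilibration series all raise named errors; collinear
superposition degrades gracefully with a flag.

## Known limitations

* MD observables of the reference study (RMSD 0.37 ± 0.03 nm for the
  nominated analog, SASA/Rg/H-bond tables), its MM/GBSA scores and its DFT
  energies depend on 100-ns trajectories and QM runs that are not
  redistributable; they enter only as ingested fixtures for ranking, never
  as recomputation targets.
* Descriptor generation from structures (SMILES/SDF) is intentionally out
  of scope; profiles are ingested tables.
* The funnel is sequential and hard-eliminating; no Pareto or probabilistic
  triage.
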
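---
title: "pocketfp: methods, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pocketfp: methods, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## What the package computes

`pocketfp` analyses protein–ligand complexes over molecular-dynamics
trajectory frames. It operates entirely on geometry: multi-model PDB
coordinates plus a user-supplied annotation of the ligand's
interaction-capable atoms. It does not run MD, docking, or quantum
chemistry — it consumes their outputs. Four layers sit on the shared
trajectory data model:

1. **Interaction fingerprinting** — per-frame detection of hydrogen bonds,
   water-mediated bridges, ionic (salt) bridges, hydrophobic contacts and
   π-π / π-cation stacking, aggregated into per-residue contact
   frequencies and persistence timelines.
2. **Trajectory statistics** — Kabsch least-squares superposition, RMSD
   time series and per-residue RMSF profiles.
3. **Pose clustering** — average-linkage hierarchical clustering of ligand
   poses with medoid (representative-complex) selection.
4. **Reactivity descriptors** — conceptual-DFT global indices (IP, EA,
   gap, hardness η, softness S, electronegativity χ, electrophilicity ω)
   of a compound from species total energies or frontier-orbital energies.

A synthetic binding-pocket generator with *planted* interactions provides
ground truth for validating every layer.

## Reactivity descriptors

Given total energies of the neutral molecule A, its cation radical A⁺ and
anion radical A⁻ (eV or Hartree; 1 Hartree = 27.211386 eV):

- IP = E(A⁺) − E(A)
- EA = E(A) − E(A⁻)

The EA convention is chosen so that EA is *positive* for
electron-binding species (the standard adiabatic electron affinity). The
Koopmans route (`descriptors_from_orbitals()`) instead takes
IP = −ε~HOMO~, EA = −ε~LUMO~. Derived indices:

- gap = EA − IP (signed; `abs_gap` = |IP − EA| is the conventional
  positive HOMO–LUMO gap — both are reported because practice differs on
  which sign is quoted),
- η = (IP − EA)/2, S = 1/(2η), χ = (IP + EA)/2, ω = χ²/(2η).

When IP = EA the hardness vanishes and S and ω are undefined; the package
returns them as `NA` with a classed warning rather than failing, so the
remaining well-defined fields are still usable. The calculator is agnostic
about whether the energy columns are electronic energies or enthalpies —
it consumes whatever the user's quantum-chemistry workflow produced.

## Geometric interaction criteria

All thresholds live in one `interaction_criteria()` object (Å, degrees):

| parameter | default | role |
|---|---|---|
| `hbond_max_HA` | 2.5 | H···A distance ceiling for hydrogen bonds |
| `hbond_min_DHA` | 120 | minimum donor–H–acceptor angle |
| `hbond_min_HAX` | 90 | minimum H–acceptor–neighbor angle |
| `water_max_HA` | 2.8 | relaxed H···A ceiling for water-bridge legs |
| `water_min_DHA` | 110 | relaxed D–H–A minimum for water-bridge legs |
| `water_min_HAX` | 90 | H–A–X minimum for water-bridge legs |
| `ionic_max` | 3.4 | closest-atom ceiling between opposite charges |
| `hydrophobic_max` | 3.6 | closest-atom ceiling between hydrophobes |
| `pi_max` | 4.5 | ring-centroid / charge-center ceiling |

Design decisions worth knowing:

- **The H-bond distance is H···A, not donor···acceptor.** A 2.5 Å
  donor–acceptor separation would be sterically impossible, so the ceiling
  is applied to the hydrogen–acceptor distance. Consequently explicit
  hydrogens are required; the detector raises a capability error if an
  H-bond-capable system carries no hydrogens at all.
- **Both angle clauses are minima and are combined conjunctively** when
  the acceptor has bonded neighbors X (D–H–A ≥ 120° *and*
  min~X~ H–A–X ≥ 90°). The disjunctive reading (either angle suffices) is
  available as `hbond_angle_mode = "or"`; it only widens the event set.
- **π criteria are centroid-distance only.** No ring-plane angle filter is
  applied by default, and one `pi_max` covers both π-π and π-cation
  pairings. π-cation considers cations only, in either orientation
  (ligand ring vs protein cation and vice versa).
- **Hydrophobic contacts are capped at one event per (ligand, residue)
  per frame**, because any number of qualifying atom pairs to one residue
  describes the same burial contact. Hydrogen-bond, ionic, π and
  water-bridge events are counted per distinct site pair, which is what
  lets per-residue frequencies exceed 1 when a residue genuinely holds
  several simultaneous contacts.
- **Water bridges** are composed of two hydrogen-bond legs — ligand↔water
  and water↔residue, each in either donor direction — both under the
  relaxed water thresholds, and each event records its bridging water. A
  triple reachable through both water hydrogens is still one event.
- Event ordering is deterministic (kind, residue, ascending atom index),
  so repeated runs produce byte-identical tables.

## Contact frequencies

`aggregate_contacts()` divides the total event count of each
(residue, kind) key by the number of frames. The semantics are exact by
construction: a contact present in 250 of 1000 frames scores 0.25 (a
quarter of the simulated time), a contact held throughout scores 1.0, and
two persistent hydrogen bonds to one residue score 2.0. The identity
`value × n_frames = count` is integer-exact and is asserted in the tests.

## Pharmacophore typing

Protein residues are typed from a shipped JSON template table
(`inst/extdata/residue_templates.json`, user-extensible): backbone N is a
donor when an amide hydrogen is present (PRO excluded) and backbone O an
acceptor; side chains contribute donors (found geometrically: element-H
atoms within 1.3 Å of the donor heavy atom in frame 1), acceptors with
their bonded neighbors, aromatic rings (PHE, TYR, TRP ×2, HIS), fixed
formal charges (LYS +1, ARG +1, ASP −1, GLU −1; termini ignored) and
hydrophobes (the side-chain carbon/sulfur atoms of ALA, VAL, LEU, ILE,
MET, PRO, PHE, TRP, TYR, CYS). HIS is treated as a neutral π ring with
donor/acceptor nitrogens — protonation-state inference is out of scope.
Waters contribute an acceptor oxygen and one donor pair per hydrogen.
Nonstandard residues are skipped with a warning. The hydrophobe
definition is atom-based rather than residue-based so that the 3.6 Å
criterion remains a strictly geometric, testable predicate.

## Superposition, RMSD, RMSF

`kabsch_superpose()` solves the weighted least-squares rigid-body problem
by SVD of the covariance matrix, with the determinant sign corrected so
reflections are never returned. Collinear or <3-point selections raise a
degeneracy error (the rotation is not unique there). RMSD series align
every frame to the reference frame (frame 1 by default — the choice is
configurable since conventions differ) on an alignment selection, then
measure RMSD over a possibly different selection *without a second fit*:
with ligand heavy atoms measured after protein-Cα alignment the series
reports the ligand's drift inside the pocket, deliberately not refitting
the ligand. Mass weighting is off by default — unweighted RMSD is the
simpler contract and the difference is negligible for Cα-based series.

RMSF aligns all frames, then takes the root-mean-square deviation of each
atom about its mean aligned position, reported per residue at Cα. Under
isotropic per-coordinate Gaussian jitter of width σ the profile converges
to σ√3; the fit itself absorbs ~6 of the 3N coordinate degrees of freedom,
so small alignment sets bias RMSF low by ≈ √(1 − 2/N) — use a generous
alignment selection when comparing to the closed form. An optional
mean-structure reference performs one re-alignment pass against the mean.

## Pose clustering

`cluster_ligand_poses()` analyses every `stride`-th frame (default 10 —
the conventional reading of clustering "with a frequency of 10"; a
5000-frame run yields 500 analyzed frames). All analyzed frames are
aligned on protein Cα to the first analyzed frame; the pairwise
ligand-heavy-atom RMSD matrix is then exactly the Euclidean distance of
the flattened aligned coordinates divided by √n_atoms. Average-linkage
hierarchical clustering is cut at `cutoff` (default 2.0 Å). Both the
algorithm and the cutoff are defaults chosen for robustness on pose
mixtures, not claims about any particular MD vendor's tool, and both are
exposed as configuration. The representative complex is the medoid of the
most populated cluster — the frame with minimal summed RMSD to its
cluster — with every tie broken toward the lowest frame index.

## The synthetic-data generator

`gen_pocket_trajectory()` builds a small pocket — a ligand hub, one
minimal residue (or residue + water) per planted interaction, and inert
glycine filler residues on a 16 Å shell — in which each planted
interaction toggles between an explicit *on* geometry (satisfying the
active criteria with a stated margin, e.g. H···A = 1.8 Å against the
2.5 Å ceiling) and an *off* geometry (violating them by a wide margin).
Per frame, each interaction is independently on with its probability `p`
(or exactly on a supplied frame list), and every atom receives Gaussian
jitter clamped at ±2.5σ (default σ = 0.03 Å) so that the on/off
classification is provably preserved. Feasibility is not assumed but
*validated at build time*: the detectors are run on the pure on/off
frames and must return exactly the planted event set and the empty set
respectively, otherwise the spec is rejected. The generator returns the
realized per-frame states as ground truth, so detector output can be
compared frame-by-frame against truth, not merely in aggregate.

`gen_two_state_trajectory()` produces a rigid 8-atom ligand hopping
between two poses (default 70/30 mixture, 5 Å apart, 0.3 Å jitter) inside
a static 20-residue backbone ring — the test bed for clustering recovery.

What the generators deliberately do **not** emulate: force-field physics,
correlated motions, periodic-boundary artifacts, protonation dynamics,
or realistic side-chain packing. Passing tests on synthetic pockets
therefore demonstrates the *geometric correctness and statistical
semantics* of the analysis, not its behavior on every pathology of real
trajectories (crowded waters, near-threshold flicker, imaging errors).

## Numerical choices and degenerate inputs

- Distances compare with strict `<` for the H···A and hydrophobic
  ceilings and `≤` for ionic and π ceilings, matching how each criterion
  is stated; angle thresholds are inclusive minima.
- Coordinates are Å throughout; PDB output carries three decimals, so
  round trips are exact to 10⁻³ Å.
- Hartree→eV uses the fixed factor 27.211386.
- Degenerate cases fail loudly and early: zero-spread or collinear
  superposition selections, stride ≥ n_frames, empty selections, zero
  frames in aggregation, annotations naming unknown atoms (all offenders
  listed), inconsistent atom counts across PDB models (offending model
  named).
- Determinism: one seeded random stream per generation call (the caller's
  RNG state is saved and restored), deterministic event ordering, and
  manifest checksums make rerun-identity testable byte-for-byte.

## Validation scale

The shipped tests and the acceptance script exercise: 200 random
mixed-site frames (~160 atoms) against exhaustive brute-force detector
oracles; 1000-frame pockets for frequency semantics and binomial
recovery at p = 0.1/0.25/0.6; 1000 random compounds for descriptor
identities (to 10⁻¹²) and 200 for Hartree/eV route agreement (to
10⁻⁹ eV); 100 random rigid transforms of 50-point sets (recovery to
10⁻¹⁰ Å); a 2000-frame σ = 0.5 Å jitter trajectory for the RMSF closed
form (within 5%); and ten 5000-frame two-state mixtures for clustering
recovery. These sizes were chosen to give tight statistical bounds while
keeping a full run in the order of a minute.

## Known limitations

- No periodic-boundary handling: trajectories must be imaged/whole.
- No binary trajectory formats (DCD/XTC) — multi-model PDB only.
- No pKa/tautomer/metal handling in typing; formal charges are template
  constants.
- Interaction detection is purely geometric; no force-field energies,
  MM-GBSA scoring or halogen-bond class.
- The ligand annotation is the user's responsibility; the package
  validates names but cannot perceive chemistry from coordinates alone.
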
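---
title: "Methods: interface persistence, fragment screening and thermal-shift analysis with gtusc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interface persistence, fragment screening and thermal-shift analysis with gtusc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gtusc)
```

## Scope and scientific background

Microtubules are nucleated from templates built around γ-tubulin and its
associated γ-tubulin complex proteins (GCPs). The contact surface between
GCP4 and γ-tubulin carries a druggable pocket that only exists once the two
proteins associate, which makes the interface an attractive target for
fragment-based lead discovery: disrupting or destabilising the complex is
expected to impair microtubule nucleation.

`gtusc` implements the computational stages of a screening campaign against
such an interface as reusable, tested components:

1. **structio** — I/O for multi-model PDB trajectories, PDBQT docking pose
   files with per-model energies, fragment property tables and DSF plate
   CSVs.
2. **contacts** — persistent intermolecular contact analysis of MD
   trajectories, superposition-corrected RMSD series, residue-pair
   histograms, interface residue lists and greedy frame clustering.
3. **fragments** — physicochemical library filtering and property
   distribution summaries.
4. **dockrank** — docking pose clustering, representative selection,
   compound ranking, binding-pocket residue enumeration and grid boxes.
5. **thermofluor** — Boltzmann melt-curve fitting, ΔTm thermal shifts and
   stabilizer/destabilizer screen classification.
6. **synthgen** — synthetic-data generators producing every input format
   with machine-readable ground truth.

Running the MD simulation, the docking engine, loop modelling and pocket
prediction are deliberately out of scope: trajectories, pose files and
descriptor tables are *inputs*.

## Persistent contact analysis

The core statistic is simple and deliberately model-free. For a chosen
chain pair, every frame of the analysis window is scanned for atom pairs —
one atom per chain — whose Euclidean distance lies within a threshold
(default **3 Å**; results are typically insensitive between 3 and 5 Å for a
packed interface). For every atom pair ever seen in contact, the fraction
of window frames in which the contact is present is computed; pairs whose
fraction **strictly exceeds** the persistence threshold (default **0.90**)
are reported as persistent.

Boundary semantics deserve care and are pinned by tests:

* the distance comparison is **inclusive** (`d ≤ 3 Å` counts as a
  contact); whether a strict comparison was intended at exactly 3.000 Å is
  not decidable from a distance histogram, and the inclusive reading is the
  conventional one;
* the persistence comparison is **strict** (`fraction > 0.90`): a pair
  present in exactly 90 % of frames — 90 of 100 — is *not* persistent.

Contact identity is the **atom pair**, not the residue pair: persistence of
each atomic distance is tracked across the trajectory, and only afterwards
aggregated. `residue_histogram()` computes, per residue pair, the fraction
of frames with *at least one* atomic contact — a union, so a residue pair
can be persistent through alternating atom pairs even when no single atom
pair is. The test suite asserts the resulting domination property
(residue-level fraction ≥ every atom-level fraction).

Hydrogens are **included** by default: the simulated systems are all-atom
and contacts are scored at atomic level. A `heavy_only` flag restricts the
scan to heavy atoms. Restricting a contact table to polar atoms
(`polar_contact_subset()`) yields a subset of the full list — the relation
a distance-plus-geometry hydrogen-bond finder bears to a pure distance
scan; angle-based hydrogen-bond criteria are not implemented.

**Analysis window.** A long MD run needs an equilibration period; for a
10 ns trajectory of this tetramer roughly the first 3 ns. The default
window therefore skips the first 30 % of frames, expressed as a fraction so
it scales to synthetic trajectories, and every function accepts an explicit
window because whether a persistence denominator should count the full run
or only the production segment is a choice the analyst must own.

## Superposition and RMSD series

`superpose()` is a least-squares rigid-body fit (Kabsch, via SVD) with
reflections excluded by construction; selections with fewer than three
atoms or collinear geometry are rejected rather than resolved by an
arbitrary tie-break. The fit is cross-checked in the tests against a
brute-force rotation-grid search and against an independent
structural-fitting routine.

`rmsd_series()` corrects for global tumbling the way trajectory deviation
plots are usually made: each frame is superposed onto the reference using
**all** atoms, then the RMSD of each named group (a chain, an interface
set) is measured in that common frame **without per-group refitting**, so
group curves remain comparable.

## Frame clustering

`cluster_frames()` uses greedy centroid clustering under superposition
RMSD: a frame joins the first cluster whose centroid lies within the
cutoff (default **1.5 Å**), else seeds a new cluster; centroids are running
means of superposed member coordinates, and each cluster's dispersion is
the mean member-to-centroid RMSD. Published workflows often use `kclust`
from the MMTSB toolset here; its exact parameters are rarely stated, so
this simpler greedy scheme is adopted as a documented stand-in — on the
case that matters for receptor selection (a stable segment forming a
single cluster) the two give identical output: one cluster whose
dispersion summarises the segment's breathing.

## Fragment filtering

The library filter is a set of **inclusive** ranges over vendor-supplied
descriptors: MW 200–500 Da, logP −5–2, molar refractivity 40–130 m³·mol⁻¹,
total atom count 20–70, PSA ≤ 200 Å². "From X to Y" phrasing leaves
strictness open; the inclusive reading is conventional and every boundary
value is tested. Descriptors are **inputs**: recomputing logP or PSA would
silently substitute one prediction model for another, so the module
filters tables as provided.

One internal inconsistency of the source screen is worth surfacing: a
filter capping logP at 2 cannot produce a library whose *average* logP is
3, yet both numbers are printed in the originating study. The package
implements the stated filter and leaves the discrepancy alone — reconciling
it would require information that was never published.

## Pose clustering and ranking

Docked poses of one compound share the receptor coordinate frame, so
pose–pose RMSD is computed **without superposition** (superposing would
erase exactly the translational differences that distinguish binding
sites). Equivalent-atom symmetry corrections are not applied; for rigid
fragments the error is small, and the limitation is stated rather than
hidden.

Clustering is greedy and energy-ordered: poses are visited by ascending
docking score, each joining the first cluster whose seed (its
lowest-energy member, hence its representative) lies within the cutoff.
The cutoff defaults to **2.0 Å** — the common docking-community choice; no
published value exists for the originating screen, so pipeline runs should
record the value used. The hit of a compound is the lowest-energy
conformation of the largest cluster, with size ties broken by better
energy, then lexicographically, so selection is deterministic.

Compound ranking resolves "best energies and most conformations" as
**cluster-size-first, then energy, then compound id** — a total order, so
the ranking is invariant under input permutation (asserted by an exhaustive
tuple-sort oracle in the tests).

`pocket_residues()` enumerates receptor residues with any atom within a
cutoff (default **4.0 Å**, the usual contact-footprint choice; no cutoff is
printed for the published pocket composition) of any pose atom, reported
per chain as collapsed range strings ("515-536, 617-632").
`residue_span_length()` does the inverse arithmetic (a 328–342 helix spans
15 residues). Grid boxes follow the AutoDock convention of
`floor(size/spacing) + 1` points per axis.

## DSF melt-curve fitting

Dye-based thermal shift assays report protein unfolding as a rising
fluorescence sigmoid. The model is the four-parameter Boltzmann curve

$$F(T) = F_{min} + \frac{F_{max} - F_{min}}{1 + e^{(T_m - T)/a}}$$

with the melting temperature $T_m$ at the midpoint and slope parameter $a$
(°C). Fitting is nonlinear least squares (Levenberg–Marquardt, 500
iteration cap, `ftol` 1e-10). Three practical choices matter:

* **Window truncation.** SYPRO-Orange-type signals decay after the
  unfolding transition as dye dissociates; the fit window runs from the
  scan start to the temperature of maximum fluorescence, and the window
  used is recorded in the fit object.
* **Deterministic initialisation.** $T_{m,0}$ at the maximum first
  difference of the 5-point-smoothed signal, baselines at the window
  extrema, $a_0 = 2$ °C. No random restarts, so fits are reproducible
  without a seed.
* **Honest failure.** A fit is `converged` only when the optimiser
  converges *and* the parameters are physically sensible
  ($F_{min} < F_{max}$, $a > 0$, $T_m$ inside the window). Flat or
  degenerate curves are reported as failed, never dropped; downstream
  classification carries them as `fit_failed`.

$T_m$ is invariant under affine rescaling of the fluorescence (gain and
offset), which the tests assert — instrument units therefore never matter.

Replicate wells of one condition are fitted independently and combined as
mean ± standard error. Thermal shifts are
$\Delta T_m = T_m(\text{condition}) - T_m(\text{reference})$; conditions
shift classification at a configurable threshold — **2 °C** is the default
"best hit" cut, with **1 °C** the usual any-effect tier, and the threshold
must be chosen explicitly for any re-analysis because published screens
rarely print the cut that separates "no effect" from "significant".

## The synthetic-data generators

Every stage is testable without external data because `synthgen` emits the
same formats the pipeline reads, with ground truth:

* **Trajectories** — two chains of minimal 3-atom residues, residues 10 Å
  apart, chains 12 Å apart, so all intermolecular distances sit far above
  the contact threshold except planted pairs. Each planted contact is
  realised in *exactly* `round(fraction × n_frames)` frames, chosen by
  seeded permutation rather than blockwise so persistence is insensitive
  to window placement; contact atoms are placed exactly (jitter applied
  elsewhere), making per-frame contact status a construction guarantee.
  Optional rigid global motion exercises the superposition correction.
  Minimal residues keep the all-pairs brute-force oracles cheap.
* **Pose sets** — spatial families `separation_A` apart whose members are
  rigid translations of one ligand by at most `jitter_A`, bounding
  intra-family RMSD by `2 × jitter_A`; any cutoff between that and the
  separation recovers the planted sizes exactly. Energies are inputs (the
  scoring engine is out of scope); the default gives the intended hit
  family a best score of −11.0 kcal/mol, a typical best pocket score in
  this kind of screen.
* **Property tables** — exactly `in_range_count` records inside every
  filter range, every other record violating at least one recorded
  descriptor; pass counts are thus exact ground truth.
* **DSF plates** — Boltzmann curves at planted $T_m$ values over the
  standard melt scan (20 → 89.9 °C every 0.3 °C; both endpoints lie on the
  grid, giving 234 readings per well), an optional linear post-peak decay
  ramp (2 % of amplitude per °C) to exercise window truncation, and
  Gaussian noise whose default (90 AU, 1 % of the default amplitude) is
  typical of plate-reader melt data. Default planted conditions used in
  the acceptance analysis mirror the measured system: γ-tubulin 33 °C,
  GCP4 42 °C, the 1:1 complex 45 °C, the pocket-closing S623R mutant
  51 °C alone and 54 °C in complex, in triplicate; the fragment screen
  plants 2 stabilizers, 8 destabilizers and 10 inactive compounds out of
  20.

All generators are deterministic given a seed and restore the caller's RNG
state.

What the generators deliberately do **not** emulate: force-field physics
(jitter is isotropic Gaussian, not correlated dynamics), realistic
chemistry of property tables, solvent, or the asymmetry of real melt
transitions. Passing tests therefore demonstrate the *analysis* is correct
under known ground truth — they do not validate force fields, docking
scores or instrument behaviour.

## Problem sizes and numerical tolerances

The shipped tests and the acceptance analysis use sizes a laptop handles
in seconds while keeping every oracle exact: 100-atom frames for
all-pairs contact oracles, 100–200-frame trajectories, a 50,000-record
library filtered to 500, 20-model pose sets (a docking engine's usual
maximum output), 50-compound rankings, and full-resolution 234-point melt
curves in triplicate. PDB round trips are asserted at 1e-3 Å (the format's
coordinate precision), superposition against brute force at 1e-6 Å,
noiseless melt-curve recovery at 1e-6 °C, and noisy recovery at 0.3 °C —
one temperature step of the scan.

## A worked micro-example

```{r example}
g <- gen_trajectory(trajectory_spec(
  n_frames = 100L, n_residues = 6L,
  planted = data.frame(res_i = 1:4, res_j = 1:4,
                       fraction = c(0.89, 0.90, 0.95, 1.0),
                       distance_A = 2.5),
  seed = 42L))
pc <- persistent_contacts(g$traj, c("B", "D"), threshold_A = 3.0,
                          persistence = 0.90, window = 1:100)
pc[, c("chain_i", "resno_i", "name_i", "chain_j", "resno_j", "name_j",
       "persistence_fraction")]
interface_residues(pc)
```

Only the 0.95 and 1.0 contacts survive the strict 90 % rule — the planted
0.90 pair is present in exactly 90 of 100 frames and is correctly
excluded.

## Known limitations

* Binary trajectory formats (DCD/XTC) are not read; convert upstream.
* No symmetry-corrected pose RMSD; no angle-based hydrogen-bond criteria.
* Thermal shifts are reported as ΔTm only — no thermodynamic ΔG or $K_d$
  extraction, which requires titration data this assay does not provide.
* The frame-clustering algorithm is a documented greedy stand-in for
  toolset-specific clustering programs; cluster *counts* can differ from
  other algorithms on marginal multi-cluster data even though the
  single-cluster case is identical.
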
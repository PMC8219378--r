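---
title: "Membrane-tether trajectory analysis: models, metrics, and the synthetic generator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Membrane-tether trajectory analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memtether)
```

# The scientific problem

Rho-family GTPases that bind the plexin receptor's Rho-GTPase-binding
domain (RBD) regulate plexin signaling in opposite directions despite
binding the RBD in nearly identical modes. A structural explanation holds
that the difference lies at the *membrane*: a GTPase with a short
C-terminal tail and a positively charged surface patch (the RhoD
phenotype) is pressed against the inner leaflet and engages it through a
specific interface around its insert (alpha-I) and alpha-4 helices,
whereas a homolog with a long flexible tail and no basic patch (the RND1
phenotype) floats above the membrane and contacts it only loosely.

Establishing this from molecular trajectories requires a specific set of
observables, and this package implements them as reusable, tested
components:

1. **Contact areas** via solvent-accessible surface area (SASA)
   differences, the quantity MD practitioners obtain from `gmx sasa`;
2. **Alignment-frame RMSD observables** — superpose each frame on a
   reference using one atom group, measure the unfitted RMSD of another —
   which turn raw coordinates into positional/stability readouts;
3. **Per-residue lipid-contact metrics** with a molecule-level 5 Å
   criterion and a 30% burn-in, plus contact maps and contact-residue
   counts;
4. **Lipid-type enrichment** at the protein–membrane interface, the
   signature of electrostatically driven binding to anionic lipids
   (POPS, PIP2);
5. A **sequence census** of charged residues in a membrane-interface
   window of a Rho-family alignment together with C-terminal tail
   lengths;
6. A **coarse-grained Monte Carlo generator** of membrane-tethered-domain
   trajectories that stands in for microsecond MD so that all of the
   above can be exercised, tested, and demonstrated at desk scale.

# Observables

## SASA and contact area

SASA uses the Shrake–Rupley construction: each atom's van der Waals
sphere is inflated by the probe radius (default **1.4 Å**, the universal
water-probe convention), quasi-uniform points are placed on it by a
golden-spiral rule (default **960 points/atom**, giving sub-1% quadrature
error; the quadrature is fully deterministic), and a point is accessible
iff it lies outside every other atom's inflated sphere. Radii come from
the element-keyed Bondi table with a documented 1.5 Å fallback;
coarse-grained beads declare their radius explicitly
(`synth_radius_table()`). Occlusion is evaluated only within the selected
subset (the subset is treated as an isolated, whole molecule; no periodic
images), matching how `gmx sasa` is typically applied to clustered
molecules.

The contact area between disjoint groups A and B is

$$\mathrm{CA} = \tfrac12\left(\mathrm{SASA}_A + \mathrm{SASA}_B -
\mathrm{SASA}_{A\cup B}\right),$$

half the buried surface, so one interface is counted once. Slightly
negative values can occur for adjacent-but-not-touching groups — a known
irregularity of SASA-difference areas — and are deliberately *retained*
in time series rather than clipped, so distributions keep their true
shape.

## Alignment-frame RMSD

`rmsd_series()` implements the align-then-measure protocol: a Kabsch fit
(SVD with the reflection branch corrected by sign-flipping the smallest
singular vector, so chirality is preserved) over the *alignment*
selection maps each frame onto the reference frame (default: the first
frame, i.e. "with respect to initial positions"); the unfitted RMSD of
the *measurement* selection is then reported. RMSD is unweighted — the
conventional choice when only C-alpha atoms are measured; mass weighting
is intentionally absent. When alignment and measurement selections
coincide (the `dimer_helices` preset) the value is the Kabsch-minimal
RMSD of that atom set, a dimer-interface stability gauge.

Distribution summaries report the mean and the **population** standard
deviation (the spread of the realized series, not an n−1 estimator of a
hypothetical population), so test expectations are exact. Correlations
between two series require exactly shared time axes — both series must
come from the same frames; no interpolation is ever performed silently.

## Lipid contacts and enrichment

A lipid *molecule* is a `(chain, residue id, residue name)` triple — the
PDB convention of one residue per lipid. A molecule is in contact with a
protein residue when **any** of its atoms lies within the cutoff
(default **5 Å**, closed boundary: ties count as contacts, a measure-zero
but deterministic choice) of **any** atom of the residue, under the
minimum-image convention whenever the trajectory carries a box. The
per-residue profile averages these molecule counts over the frames
retained after discarding the first `ceiling(f × n_frames)` frames
(default f = **0.3**, the convention of dropping the first 30% — e.g.
0.3 µs of a 1 µs run — as equilibration; a fraction generalizes to any
trajectory length).

Enrichment of a lipid class compares the fraction of that class among
*contacting* molecules to its baseline fraction in the whole lipid
selection. Frames with an empty contacting set are recorded as missing,
not zero: the composition of an empty set is undefined, and zeros would
bias the ratio downward.

## Sequence census

The interface window is specified in the *ungapped* numbering of a
reference sequence (e.g. the alpha-I helix, reference residues 130–146,
plus an alpha-4 range) and mapped to alignment columns; each sequence's
residues in those columns are then counted with **K/R/H positive**
(histidine is counted positive because it appears among the
membrane-contacting basic residues in this system class; the rule is
applied uniformly to all sequences) and **D/E negative**; gaps contribute
nothing. Tail length is the number of non-gap residues strictly
C-terminal to the alignment column of the reference's catalytic-domain
end. The long/short tail threshold deliberately has **no library
default** — it is a reporting choice; the orchestration layer
(`run_census()`) defaults it to 8 residues. The alpha-4 window boundaries
are likewise configuration, not constants, because no authoritative range
exists. The package consumes precomputed alignments and never builds one.

# The synthetic generator

`simulate_tether()` is a deliberately minimal stand-in for microsecond
membrane MD, built so that the *analysis machinery* — not membrane
physics — can be validated end to end.

**The stated world.** The lower leaflet is a square lattice of one bead
per lipid at z = 0 with composition POPC:POPS:PIP2 = **70:25:5** over
**540 lipids** by default (so exactly **27 PIP2** beads, 5% of the inner
leaflet, the composition used when studying anionic-lipid enrichment;
`plan_membrane()` reproduces these counts by largest-remainder rounding
with ties broken in the fixed order POPC > POPS > PIP2). Nominal bead
charges are POPC 0, POPS −1, PIP2 −4 — physiological net charges; only
their ordering matters for trend observables. The GTPase catalytic domain
is a rigid golden-spiral shell of **60 beads, radius 14 Å** (the scale of
a small GTPase domain); the **12** beads of its membrane-facing polar cap
can carry **+1 e** each. A freely jointed tail of beads at **3.8 Å**
bonds (one residue per bead) tethers a fixed membrane anchor to the
lowest domain bead. Electrostatics are Debye–Hückel screened Coulomb with
Debye length **7.9 Å** (150 mM monovalent salt) and dielectric **80**;
excluded volume is a soft-core repulsion of protein beads against lipid
beads and the z < 0 half-space; bonds are harmonic (10 kT/Å²). Energies
are in kT; the Coulomb prefactor 560.47 e⁻²·Å·kT is the 300 K value.
Because beads are finite spheres and the soft core is finite, the
screened Coulomb distance is clamped at the bead contact distance
(2 × bead radius): without the clamp the point-charge 1/r singularity
would overpower any finite repulsion and oppositely charged beads would
collapse onto each other — a defect surfaced by the energy-oracle and
acceptance-rate checks, not a tunable.

**Presets.** `rhod_like_config()` = 12 × +1 patch, 4-bead tail;
`rnd1_like_config()` = no patch charge, 14-bead tail. These encode the
two phenotypes whose contrast the analysis stack is meant to expose.

**Sampling.** Metropolis Monte Carlo with symmetric proposals: rigid
domain translations (≤1 Å) and rotations about the domain center (≤5°),
plus per-tail-bead crankshaft rotations (≤30°) *and* single-bead
displacements (≤0.5 Å). The displacement move matters for correctness:
crankshaft rotations preserve the distances to both bonded neighbours, so
without displacements the tail bond lengths would stay frozen at their
initial values and the chain would not be ergodic — this was caught by
the direct-sampling cross-check below. Monte Carlo was chosen over
Langevin dynamics precisely because its stationary distribution is exact,
enabling an independent oracle: configurations of the zero-charge tether
model can be drawn directly by chain-growth (bond vectors sampled from
their exact Boltzmann densities) plus rejection on the remaining energy,
and the MC height distribution is required to agree by a two-sample KS
test. The time axis is the sweep index, labelled ns nominally.

Determinism: one seeded generator stream drives lipid-type shuffling,
move proposals and acceptance draws in documented order, so an identical
configuration reproduces a trajectory bit for bit. Trajectories can be
written as multi-model PDB (lipids as POPC/POPS/PIP2 residues, each
domain bead its own single-residue "protein" entry on chain A), so every
analysis function runs unchanged on files as on in-memory objects.

**What the generator does *not* emulate.** Lipids are immobile (no
lateral diffusion, no leaflet exchange, no membrane elasticity); the
upper leaflet, solvent and ions are implicit; the domain is perfectly
rigid; the tail is uncharged; there is no RBD/plexin — the *only*
restraint on the domain is the tether and the membrane itself; absolute
energies and contact-area magnitudes are not calibrated to the atomistic
system. A green directional test therefore establishes that the metrics
recover the stated mechanism *in this stated world*, not that the world
reproduces atomistic physics. The tail's initial conformation is a
straight interpolation between anchor and attachment (bonds start
compressed); the Metropolis chain relaxes this within tens of sweeps and
all burn-in-aware summaries discard the transient.

# Numerical choices and edge cases

* Distance criteria use closed boundaries (≤ cutoff); contacts at exactly
  the cutoff are contacts.
* Burn-in discards `ceiling(f × n)` frames; `f = 0` discards none;
  a burn-in leaving zero frames is an error, never an empty average.
* `neighbor_pairs()` is an exact cell list; with a periodic box the
  cutoff must not exceed half the shortest box length (minimum-image
  validity is checked, not assumed). Orthorhombic boxes only.
* Kabsch requires ≥3 non-collinear points in both point sets; degenerate
  alignments raise errors rather than returning arbitrary rotations.
* Coincident identical atoms in SASA are handled (strict-inequality
  occlusion leaves them exposed); NaN coordinates are errors.
* PDB reading keeps the first alternate location and rejects insertion
  codes outright — synthetic data never produces them and silent
  ambiguity is worse than failure. Residue numbering is author
  numbering, 1-based, ranges inclusive.
* Frame times default to `frame index × stride` (stride is configuration;
  a saving stride is never inferred from a file).
* Zero-variance series have undefined correlations, reported as `NA`;
  Spearman uses average ranks for ties.

# Open design decisions

* Whether trajectory RMSDs should be mass-weighted is unstated in common
  protocols; unweighted is the default here and the selection strings
  decide which atoms participate.
* Whether contact-area/RMSD correlations should pool replicas or be
  computed per run: both are possible (`correlate_series()` is per-run;
  pooling is a caller-side concatenation), neither is privileged.
* The 5 Å contact criterion uses all atoms of residue and lipid;
  restricting to heavy atoms is a selection-string choice, not a code
  path.
* Ion planning (`plan_ions()`) converts concentration to pairs via the
  55.345 mol/L molarity of water, then neutralizes net solute charge by
  raising the counter-ion count — the conventional system-construction
  arithmetic.

# Known limitations

Triclinic boxes, mmCIF, compressed/binary trajectory formats, leaflet
assignment, lipid order parameters, membrane curvature, and electrostatic
surface maps are out of scope. The SASA implementation has no periodic
images, so selections spanning a periodic boundary must be made whole
first. The generator's Monte Carlo "time" has no physical time scale;
only stationary distributions and directional contrasts are meaningful,
never kinetics.
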
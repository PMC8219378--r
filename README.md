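# memtether

Trajectory and sequence analysis for membrane-tethered GTPases — the
observable set with which one asks *how* a Rho-family GTPase bound to a
receptor such as plexin engages the inner leaflet of the cell membrane,
and whether that engagement is driven by a positively charged surface
patch and a short C-terminal tether (the RhoD phenotype) or absent in a
long-tailed, neutral-interface homolog (the RND1 phenotype).

## Who it is for

Structural bioinformaticians and molecular modellers who have (or want to
emulate) trajectories of a protein near a membrane and need the standard
quantitative readouts as tested, composable functions rather than
one-off scripts.

## What it computes

**Contact areas (SASA difference).** Shrake–Rupley solvent-accessible
surface area with a deterministic golden-spiral quadrature
(`sasa()`), and the interface area between two disjoint groups

&nbsp;&nbsp;CA = ( SASA_A + SASA_B − SASA_{A∪B} ) / 2,

per frame as a time series (`membrane_contact_area_series()`). Probe
1.4 Å, Bondi radii, 960 points/atom by default.

**Alignment-frame RMSD.** `rmsd_series()` superposes each frame on a
reference frame by a Kabsch fit over one selection (e.g. the C-alpha
atoms of a receptor domain) and reports the unfitted RMSD of another
selection (e.g. the GTPase) against its initial position —
RMSD(t) = min over rigid motions fitted on the *align* set, measured on
the *measure* set. Presets cover GTPase-vs-GAP, GTPase-vs-RBD,
RBD-vs-GAP and dimerization-helix observables; `summarize_series()`
gives distribution mean and population spread; `correlate_series()`
gives the contact-area↔RMSD Pearson/Spearman correlation.

**Lipid contacts.** A lipid *molecule* counts for a protein residue when
any of its atoms is within 5 Å of any atom of the residue (minimum-image
aware). Per-residue burn-in-averaged profiles
(`residue_lipid_contacts()`, first 30% of frames discarded by default),
full residue × time contact maps (`contact_map()`), per-frame counts of
membrane-contacting residues (`contact_residue_count_series()`), and
anionic-lipid enrichment at the interface (`lipid_enrichment()`:
fraction of POPS/PIP2 among contacting molecules over their leaflet-wide
fraction).

**Sequence census.** `census_table()` counts positively (K/R/H) and
negatively (D/E) charged residues inside a membrane-interface window
given in reference-sequence numbering (e.g. the alpha-I helix, residues
130–146 of RhoD, plus an alpha-4 range) across a Rho-family alignment,
together with each member's C-terminal tail length and a long/short
classification.

**Synthetic trajectories.** `simulate_tether()` is a seeded,
bit-reproducible Metropolis Monte Carlo generator of a rigid bead-shell
domain with a tunable charged polar cap, tethered by a flexible tail to a
fixed anchor above an immobile POPC/POPS/PIP2 bead leaflet (70:25:5 over
540 lipids by default — 27 PIP2, 5% of the inner leaflet), under
Debye–Hückel electrostatics (7.9 Å screening, 150 mM salt). It stands in
for microsecond MD so every metric above can be exercised end to end;
`rhod_like_config()` / `rnd1_like_config()` encode the two phenotypes and
`compare_tether_systems()` runs the paired contrast with one-sided
Mann–Whitney tests. `plan_membrane()` / `plan_ions()` /
`audit_membrane()` cover the system-construction arithmetic.

I/O: (multi-model) PDB and a plain-text frame format in and out, a small
selection language (`"name CA and resid 130-146"`), TSV tables, JSON
manifests, aligned FASTA/Clustal alignments (via Biostrings).

## Worked example

```r
library(memtether)

cfg  <- rhod_like_config(seed = 42, n_sweeps = 1500)  # +12e patch, 4-bead tail
traj <- simulate_tether(cfg)
traj
#> Trajectory: 61 frames x 605 atoms, t = 0 .. 1500 ns

tm <- tether_metrics(traj, n_points = 480)
round(tm$row, 3)
#>   mean_area mean_count mean_enrichment rmsd_spread pearson_r
#> 1   227.269        3.5           1.062        1.61     0.448
tm$area_summary
#> DistributionSummary 'membrane_contact_area': mean 227.3, spread 76.75 A^2 (n = 42)
```

Reading: after burn-in this charged-patch domain buries on average
~227 Å² of surface against the membrane, keeps ~3.5 of its 60 beads
("residues") in lipid contact, contacts anionic lipids slightly above
their leaflet fraction (enrichment 1.06), and its membrane contact area
co-varies with its positional RMSD (Pearson r = 0.45) — the signature of
membrane interaction steering the domain's position. The same call on an
`rnd1_like_config()` run (neutral patch, 14-bead tail) yields a several-
fold smaller contact area and residue count.

The bundled synthetic Rho-family alignment demonstrates the census:

```r
aln <- system.file("extdata", "rho_family_synthetic.fasta", package = "memtether")
run_census(aln, ref_id = "RHOD", ranges = list(c(130, 146), c(150, 160)),
           ref_catalytic_end = 180, tail_threshold = 8)
#>     id n_pos n_neg tail_len tail_class
#>   RHOD    12     2        7      short
#>   RND1     3     5       26       long
#>   RAC1     5     3       22       long
#>   RHOA     5     4       15       long
#>  CDC42     9     2        8      short
#>    RIF     5     4       21       long
#>   RND3     4     5       31       long
```

Short-tailed members carry the more basic membrane-interface windows —
the correlation the census is designed to expose. (The alignment is
synthetic, generated by `write_example_alignment()`; it has the structure
of the real family, not its sequences.)

`run_metrics()` drives the whole pipeline (simulate or load → every
metric → TSV tables plus a JSON manifest) from one configuration list or
JSON file, resolving all selections up front so a typo fails before any
computation starts.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's headline analysis from scratch: paired
charged-patch/short-tail vs neutral/long-tail simulations across seeds,
the full membrane-observable bundle and directional Mann–Whitney
contrasts per run, and the bundled-alignment charge census, then writes
the JSON report to `--out`. All randomness derives from `--seed`.

## Vignette

`vignettes/membrane-tether-analysis.Rmd` documents the models and their
assumptions, every tunable parameter with units and defaults, what the
synthetic generator does and does not emulate (and hence what a green
test establishes), numerical edge-case policy, and known limitations.
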
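---
title: "Dynamic binding-pocket descriptors: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic binding-pocket descriptors: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pocketdyn)
```

## What the package computes

`pocketdyn` condenses a protein–ligand molecular-dynamics trajectory into a
small set of per-residue and per-complex descriptors of binding-site
dynamics, and judges a complex against cohort-derived reference ranges:

* **RMSD series and fluctuation ranges.** Every frame is superposed onto a
  reference frame (by default the first frame, i.e. the prepared pose) using
  the protein backbone as the fit group — a closed-form Kabsch least-squares
  superposition with the proper-rotation (reflection) correction. The RMSD
  of a measured group (whole backbone, the backbone atoms of one binding
  residue, or the ligand) is then computed *without refitting*. Measuring
  the ligand in the frame defined by the protein fit is what turns its RMSD
  into a pose-stability readout: a ligand that stays put in the pocket has a
  flat, low series even while the complex tumbles. The fluctuation range of
  a series is `max − min` over frames, reference included.
* **Solvent-accessible surface area (SASA).** Shrake–Rupley with a
  deterministic Fibonacci-lattice point set: for each atom, `n_points` test
  points are placed on the sphere of radius `r_vdw + probe`; a point is
  accessible iff it lies outside every other atom's expanded sphere. The
  per-residue series is the sum over the residue's atoms computed in the
  context of the full complex (ligand included as an occluder); the
  pocket-group series is the sum over all binding residues, which by
  per-atom additivity equals the SASA a trajectory tool would report for a
  binding-residue index group.
* **Hydrogen-bond existence matrix and occupancy.** Donors are N/O/S atoms
  with a covalently attached hydrogen (H within 1.2 Å); acceptors are N/O.
  A bond exists when the donor–acceptor distance is ≤ 3.5 Å and the H–D–A
  angle is ≤ 30°; structures without any hydrogens fall back to the distance
  criterion alone. The existence matrix holds one row per donor–acceptor
  pair ever observed between the binding residues and the ligand and one
  column per frame. A residue's occupancy in a frame is the union over its
  pairs ("any bond present"); its occupancy fraction is classified as low
  (≤ 0.30), moderate (≤ 0.70) or high (> 0.70), boundaries lower-inclusive.
  On a 100-frame ≈ 100 ns run these fractions reproduce 0–30 / 31–70 /
  71–100 ns time bins, and expressing them as fractions makes the
  classification independent of trajectory length.
* **Pocket composition and enrichment.** Binding residues are pooled over a
  cohort (one count per residue identity per complex) and compared with the
  whole-protein background composition: descriptive ratios, plus an exact
  two-sided binomial test per amino acid with Benjamini–Hochberg adjustment
  across the tested amino acids. The tests are an addition layered on the
  descriptive comparison and are labelled as such. The default
  physicochemical classes put histidine with the charged residues (it is
  one of the recurrently enriched pocket residues alongside aspartate and
  arginine); the class map is a plain list and can be replaced.
* **Benchmark scoring.** `default_reference()` pins the published cohort
  constants — ligand RMSD quartiles 1.0/1.6/2.0 Å, binding-residue backbone
  RMSD quartiles 0.7/1.2/1.5 Å, pocket SASA minimum quartiles
  2.29/2.68/2.72 and maximum quartiles 3.03/3.2/3.62 (in the source's
  printed units), the overall SASA range 1.9–3.92, the backbone stability
  band 1.5–4 Å, and the 86.5 % cohort share of high-occupancy residues.
  `assess()` grades a complex's descriptors against these blocks.

## Identifying binding residues

Binding residues are the protein residues with at least one detected
hydrogen bond to the ligand within an identification window of leading
frames. The window defaults to the first frame — the prepared pose, which
mirrors identifying the pocket on the relaxed structure before the
production run — and can be widened to the whole trajectory to catch
residues that only engage later. An optional hydrophobic-contact detector
(apolar carbon pairs within 4.0 Å) can widen the pocket definition; it is
off by default because the descriptors are hydrogen-bond-centric. An empty
result is always an explicit warning, never a silent empty table.

## Units, and the SASA reference scale

Coordinates are Å everywhere; frame times are frame units unless a stride
(time per frame) is configured; SASA is Å². The reference's SASA constants
are stored verbatim in the source's printed units. Printed values of
1.9–3.92 "Å²" are physically implausible for amino-acid residues — a single
fully exposed residue reaches roughly 150–200 Å² — but match the nm²
convention of common MD tooling when the quantity is the *binding-residue
group total*: ×100 gives 190–392 Å², exactly the scale of a two-to-four
residue pocket group. `assess()` therefore compares the pocket-group SASA
extrema after multiplying the reference by a configurable `sasa_factor`
(default 100), and every report states this assumption. Setting
`sasa_factor = NA` makes the mismatch a hard error; `1` compares raw
printed units.

Two further inconsistencies in the printed constants are resolved the same
way throughout: the maximum-SASA IQR is quoted as both 0.6 and 0.59, and the
quartiles 3.03/3.62 derive 0.59, which is what the reference stores; a
restatement of the backbone band as "0.15–0.4 Å²" is a unit slip for the
1.5–4 Å band, which is used.

## The verdict rule

The published material proposes reference ranges but no decision rule, so
the three-level verdict is this package's construction and is printed in
every report header. Each descriptor is graded `within_iqr` (inside
`[Q1, Q3]`), `within_whiskers` (inside the Tukey fences
`[Q1 − 1.5·IQR, Q3 + 1.5·IQR]`) or `outside`. The backbone median RMSD is
special-cased: values *below* the 1.5 Å lower edge indicate more, not less,
stability, so only exceeding 4 Å counts as outside. The overall flag is
`consistent` when nothing is outside and at least 70 % of binding residues
are high-occupancy, `inconsistent` when two or more descriptors are outside
or fewer than 30 % are, and `borderline` otherwise. The rule is monotone:
worsening any single descriptor can never improve the flag (this is covered
by a test).

## Box statistics

Quartiles use linear interpolation of the sorted sample at positions
`(n − 1)·p` — the type-7 rule, R's default — pinned for reproducibility
since several interpolation conventions exist. `box_stats` also reports the
semi-interquartile distances `median − Q1` and `Q3 − median`, the Tukey
outliers, and `n`.

## The synthetic-data generator

No trajectory data ships with the package; every test input is generated.
A synthetic complex is a caricature that preserves exactly the statistical
structure the descriptors read:

* a backbone-complete polypeptide (N, CA, C, O per residue) laid on an open
  arc with 3.8 Å CA spacing — non-self-intersecting, with real element
  labels so SASA radii and donor/acceptor typing need no special cases;
* pocket residues carry one donor-capable side-chain hydroxyl pseudo-atom
  pointing at the ligand; the ligand has one acceptor oxygen per pocket
  residue plus apolar scaffold carbons;
* frames are the reference plus independent per-atom Gaussian jitter
  (`residue_sigma`, `ligand_sigma`), with optional cumulative ligand drift
  (`ligand_drift` Å per frame along a fixed direction) emulating a ligand
  leaving the pocket;
* each pocket residue follows a hydrogen-bond schedule (target fraction
  `f`, pattern `block`, `periodic` or `random`). Schedule-critical atoms
  are placed after jitter: the donor is jittered (σ capped at 0.2 Å), the
  partner is then set at exactly 2.8 Å along the pocket axis in bonded
  frames and 6.0 Å (or its drifted free position, if farther) otherwise,
  and the hydrogen sits on the donor–acceptor axis. Bonded geometry
  therefore satisfies the criteria with margin and unbonded geometry
  violates them with margin, so the realised occupancy equals the schedule
  exactly — the property the parameter-recovery tests assert.

Defaults are a 30-residue chain with three charged pocket residues
(aspartate, histidine, arginine — the residues recurrently enriched in real
pockets), jitter of 0.25 Å, occupancy 0.9 in a block pattern, and 100
frames. All randomness flows from one seed; cohorts derive one seed per
complex from the cohort seed and the complex index, so complexes are
reproducible independently of generation order.

What the generator does **not** emulate: correlated collective motions
(jitter is independent per atom, so RMSD and SASA fluctuate less, for a
given displacement scale, than in real MD), side-chain rotamers, water,
secondary-structure topology, and chemically diverse ligands. Passing the
recovery and discrimination tests therefore shows the *pipeline* is correct
and discriminating on data with known truth — not that any particular real
complex will fall inside the reference bands.

## Numerical choices and degenerate inputs

* Kabsch: SVD of the 3×3 cross-covariance; the smallest singular direction
  is sign-flipped when the candidate rotation has negative determinant.
  Fewer than three points, or collinear point sets (second singular value
  below 1e-8), are errors rather than silently arbitrary rotations.
* Shrake–Rupley: the Fibonacci lattice is deterministic, so SASA values are
  bit-reproducible; `n_points = 960` by default (an isolated sphere is
  exact at any resolution; a packed 10-atom cluster's total moves < 2 %
  when doubling to 1920). Occluder search is pruned to atoms within
  `r_i + r_j + 2·probe`. Unknown elements get a 1.70 Å default radius with
  a warning, or an error if the default is disabled.
* Occupancy: a single-frame trajectory has occupancy 0 or 1 and all
  fluctuation ranges 0. Frame duration is the median time step (1 for a
  single frame).
* Boundary conventions: occupancy 0.30 is low and 0.70 moderate
  (lower-inclusive bins); selections are always topology-ordered; empty
  selections are errors.
* Ties in quartiles, and constant samples, follow directly from type-7
  interpolation (IQR 0, no outliers).

## Problem sizes used in the shipped checks

The test and acceptance workloads are sized for a laptop-class single CPU:
synthetic complexes of 28–35 residues with 10–25 frames for unit and
recovery tests, a 53-complex cohort (318 scheduled binding residues, 20
frames each) for the occupancy-share reconstruction, 100 replicate pairs of
25-frame complexes for the stability-discrimination check (SASA lattice at
240 points there), and 150 simulated cohorts for the false-discovery-rate
control of the enrichment tests. These sizes were chosen so the full suite
runs in a couple of minutes while keeping Monte-Carlo margins comfortable.

## Known limitations

* The interaction detector covers hydrogen bonds (and optionally
  hydrophobic contacts); π-stacking, salt bridges as a distinct type,
  halogen bonds and water-mediated bridges are out of scope.
* Insertion codes, alternate locations beyond dropping non-`A` records,
  mmCIF, and binary trajectory formats (XTC/DCD) are unsupported; the
  trajectory formats are multi-model PDB and a plain XYZ table.
* Occupancy uses cumulative frames; a longest-contiguous-stretch variant is
  not implemented.
* The reference constants come from one published 100-complex cohort;
  `read_reference()`/`write_reference()` exist precisely so users can
  re-derive and swap in their own cohort's ranges.
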
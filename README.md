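# pocketdyn

Dynamic descriptors of protein–ligand binding pockets from molecular-dynamics
trajectories, and a benchmark scorer for docking-pose reliability.

## The problem

Docking predicts where a ligand binds, but a pose that looks good in a static
structure may not survive dynamics. Across large MD cohorts of co-crystal
complexes, the residues that actually drive ligand recognition — *dynamic
hotspots* — show a characteristic signature: tight RMSD fluctuation of the
binding-residue backbone, a ligand that stays put in the pocket frame,
persistent (high-occupancy) hydrogen bonds, stable solvent exposure of the
pocket, and a strong enrichment of charged residues (Asp, His, Arg) relative
to the whole-protein background. `pocketdyn` computes exactly these
descriptors for a trajectory and compares them with published cohort
reference ranges, so users of docking + MD workflows can ask: *does my
complex behave like the stable, reliable ones?*

## The descriptors

For a trajectory with frames superposed on the first frame via Kabsch
least-squares fitting of the protein backbone (fit group), without refitting
the measured group:

* **RMSD series** for the backbone, each binding residue's backbone
  (N, CA, C, O) and the ligand; per-series **fluctuation range**
  `max − min` over frames.
* **SASA** by Shrake–Rupley (Fibonacci lattice, 960 points/atom, 1.4 Å water
  probe, Bondi radii): per-residue series in full-complex context, and the
  binding-residue group total, with min/max over frames.
* **H-bond existence matrix**: donor–acceptor pairs × frames, a bond present
  when D–A ≤ 3.5 Å and the H–D–A angle ≤ 30° (distance-only fallback for
  heavy-atom structures). Per-residue **occupancy** is the any-pair union of
  frames, classified low (≤ 0.30) / moderate (≤ 0.70) / high (> 0.70).
* **Pocket composition**: binding residues pooled over a cohort (once per
  complex) versus the whole-protein background, with descriptive enrichment
  ratios, exact binomial tests and Benjamini–Hochberg adjustment, and
  charged / polar-uncharged / non-polar class fractions.
* **Benchmark**: `assess()` grades the complex against the published cohort
  quartiles (ligand RMSD 1.0/1.6/2.0 Å; residue RMSD 0.7/1.2/1.5 Å; pocket
  SASA min 2.29/2.68/2.72 and max 3.03/3.2/3.62 in the source's printed
  units, compared after a configurable ×100 unit conversion; backbone band
  1.5–4 Å; 86.5 % high-occupancy share) and returns
  consistent / borderline / inconsistent.

A deterministic synthetic-MD generator (`complex_spec()`,
`generate_complex()`, `generate_cohort()`) builds complexes with known
ground truth — scheduled H-bond occupancies are realised *exactly* — so the
whole pipeline is testable without external data.

## Worked example

```r
library(pocketdyn)

g <- generate_complex(complex_spec(residue_sigma = 0.1, ligand_sigma = 0.1,
                                   n_frames = 25, seed = 42))
d <- complex_descriptors(g$trajectory, "LIG",
                         descriptor_config(n_points = 240), "demo")
d$residues[, c("res_name", "rmsd_range", "sasa_min", "sasa_max",
               "occupancy_fraction", "cluster")]
#>   res_name rmsd_range sasa_min sasa_max occupancy_fraction cluster
#> 1      ASP  0.3880344 103.8627 144.5516               0.88    high
#> 2      HIS  0.2914754 102.2858 142.9958               0.88    high
#> 3      ARG  0.3120099 103.7003 146.8750               0.88    high
assess(d)
#> <benchmark_report> flag: consistent
#>   rule: consistent: no descriptor outside whiskers and high-occupancy share >= 0.70; ...
#>   reference SASA stored in paper-units (presumed nm^2); compared after multiplying by 100
#>   ligand_rmsd_median        0.240  band [   1.000,    2.000]  within_whiskers
#>   residue_rmsd_median       0.206  band [   0.700,    1.500]  within_whiskers
#>   pocket_sasa_min         318.566  band [ 229.000,  272.000]  within_whiskers
#>   pocket_sasa_max         426.305  band [ 303.000,  362.000]  within_whiskers
#>   backbone_rmsd_median      0.236  band [   1.500,    4.000]  within_whiskers
#>   high-occupancy share 1.000 (cohort reference 0.865)
```

Each binding residue keeps its hydrogen bond to the ligand in 88 % of frames
(the generator scheduled 0.9 over 25 frames, i.e. 22/25), its backbone RMSD
fluctuates by < 0.4 Å, and every descriptor falls inside the reference
whiskers while all residues are high-occupancy — so the pose is flagged
`consistent`. A drifting, transiently-bonded complex
(`ligand_drift = 0.5`, `f = 0.1`) is flagged `inconsistent`.

Real data enter through `read_structure()` (PDB) and `read_trajectory()`
(multi-model PDB or a plain XYZ table), and the same pipeline runs via
`run_analyze()` / `run_aggregate()` / `run_benchmark()`, which also write
TSV reports and a parameter manifest. A thin command-line front end with
`simulate`, `analyze`, `aggregate` and `benchmark` subcommands lives at
`inst/cli/pocketdyn`.

See the vignette (`vignettes/pocketdyn-methods.Rmd`) for the models,
parameter meanings, unit conventions and design decisions.

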
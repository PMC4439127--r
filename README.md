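# memtraj

Trajectory analysis for molecular-dynamics simulations of
membrane-embedded receptors with a bound ligand, written for
structural-bioinformatics work on GPCR-class systems: how does the
lipid environment (pure POPC, POPC/POPE, cholesterol-rich) change a
receptor's fold stability and the population of its ligand binding
poses?  Answering that from raw trajectories requires a battery of
standard measurements, which this package provides as tested,
composable R functions plus a pipeline orchestrator and a
ground-truth synthetic-system generator.

## What it computes

* **Superposition & convergence** — Kabsch superposition (proper
  rotations only), RMSD/RMSF, all-to-all Cα RMSD matrices
  `M(i,j) = min_R RMSD(x_i, R x_j)`, and a quantitative verdict on the
  matrix block structure: `irreversible_transition`,
  `leave_and_return` (the converged-alike signature), or
  `undetermined`.
* **Ligand poses** — Gromos conformational clustering (greedy
  max-neighbour at an RMSD cutoff, ligand atoms after backbone
  alignment), pose populations in %, representative frames; the
  orientational flipping angle arccos(μ_τ·μ_ι) of the ligand's ring
  plane vector; the centre-of-mass cloud in the receptor-aligned
  frame; water counts in a fixed binding-cavity box; minimum-distance
  and contact-occupancy series.
* **Membrane structure** — phosphate density profile along the
  bilayer normal and leaflet-to-leaflet thickness; grid-based area
  per lipid (cells assigned to the laterally nearest P/protein atom;
  areas conserved exactly); headgroup PN tilt Φ_PN = arccos(PN̂·ẑ)
  distributions per lipid type; geometric hydrogen-bond occupancies
  (d ≤ 0.35 nm, angle ≤ 30°).
* **Lateral diffusion** — protein-proximity classification
  (within 0.35 nm, ever), lateral MSD over molecules and time
  origins with periodic unwrapping, and the 2-D Einstein relation
  MSD(Δ) = 4DΔ fitted over a 10–50% lag window.
* **Helicity timeline** — a Cα(i)–Cα(i+4) distance criterion for
  helix/coil per residue and frame, detecting programmed
  helix-to-coil transitions.
* **I/O** — fixed-column PDB (Å→nm) and GRO readers/writers,
  multi-model/concatenated trajectories, a plug-in point for external
  (e.g. XTC) backends, and deterministic atom selections over roles,
  residue ranges and atom names.
* **Synthetic systems** — `synth_config()` + generators for bilayers,
  Brownian lipids, pose-mixture ligand trajectories, helix traces and
  cavity waters, all bit-deterministic given a seed, with defaults
  matching the study conditions the analyses are meant to recover.

## Worked example

Generate a synthetic system whose ground truth mirrors the conditions
of a cholesterol-rich membrane study — a dominant ligand pose at
92.4%, area per lipid 0.61 nm², headgroup tilt 90(36)°, free-lipid
diffusion 8e-8 cm²/s — then recover those numbers with the analyses:

```r
library(memtraj)
cfg <- synth_config(seed = 1, n_frames = 200)

lig  <- make_ligand_traj(cfg)
clus <- gromos_cluster(lig, sel(role = "protein"), sel(role = "ligand"),
                       cutoff = 0.2)
print(clus)

bil <- make_bilayer(cfg, include_protein = TRUE)
apl <- area_per_lipid_grid(bil$topology, bil$frame, sel(atom_name = "P"),
                           protein_spec = sel(role = "protein"),
                           grid_n = 100)
cat(sprintf("mean area per lipid: %.3f nm^2\n", apl$apl_mean))

tr <- make_brownian(cfg, bil)
free_ids <- as.integer(names(which(attr(tr, "groups") == "free")))
est <- fit_diffusion(lateral_msd(tr, sel(residue_id = free_ids,
                                         atom_name = "P")))
print(est)
```

prints

```
pose_clustering: 3 clusters over 200 frames (cutoff 0.20 nm)
  cluster 1:  93.0%  (representative frame 29)
  cluster 2:   5.0%  (representative frame 105)
  cluster 3:   2.0%  (representative frame 3)
mean area per lipid: 0.605 nm^2
diffusion_estimate: D = 7.77e-08 cm^2/s (r^2 = 1.000)
```

The largest cluster's 93.0% is the sample estimate of the generator's
92.4% mixture weight over 200 frames; 0.605 nm² recovers the
configured 0.61 nm² within grid resolution (the protein column takes
its own share of cells); 7.77e-8 cm²/s recovers the free-group
8e-8 cm²/s within the fit's stochastic error.  The full battery —
convergence, ligand, membrane, diffusion and helicity blocks with a
provenance-stamped JSON report and TSV artifacts — runs as

```r
rep <- run_pipeline(run_config(synth = cfg), out_dir = "out")
```

and is byte-reproducible for a fixed config and seed.

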
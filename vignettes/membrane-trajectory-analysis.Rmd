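---
title: "Methods: membrane-protein trajectory analysis with memtraj"
author: "memtraj authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: membrane-protein trajectory analysis with memtraj}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memtraj)
```

## Scope and model

`memtraj` implements the analysis battery routinely applied to
molecular-dynamics trajectories of a membrane-embedded receptor with a
bound small-molecule ligand: convergence diagnostics built on
all-to-all C&alpha; RMSD matrices, Gromos conformational clustering of
ligand binding poses with population statistics, ligand mobility
measures, binding-cavity hydration, bilayer structural metrics
(phosphate density profile and thickness, grid-based area per lipid,
headgroup PN tilt, geometric hydrogen-bond occupancies) and lateral
diffusion coefficients from the 2-D Einstein relation.

Internally everything is in nanometres, picoseconds and degrees; PDB
files (&Aring;ngstr&ouml;m) are converted at the I/O boundary.  The z
axis is the bilayer normal by convention; no normal estimation is
performed, and only orthorhombic boxes are supported.  Residue
numbering is 1-based, exactly as in the source file, so published
residue-range selections can be used verbatim.  Chain roles
(protein/POPC/POPE/CHOL/water/ligand/ion) are assigned from residue
names through an editable table; an unknown residue name is an error
rather than a silent misclassification, because every downstream
metric partitions atoms by role.

## Superposition and convergence

Rigid-body superposition uses the Kabsch algorithm: SVD of the
weighted cross-covariance matrix with the usual determinant correction
so that the rotation is always proper (no reflections).  Weights
default to uniform.  The test suite cross-checks the minimised RMSD
against an independent quaternion characteristic-polynomial oracle at
1e-9 nm on a thousand random point sets.

The all-to-all RMSD matrix stores the superposed C&alpha; RMSD for
every frame pair (default stride: every 10th stored frame, to bound
the quadratic cost; the stride is recorded in the result).  The
literature reads such matrices visually: a block structure with no
similarity between early and late blocks signals an irreversible
conformational transition, whereas trajectories that leave a
conformational neighbourhood and later return to it ("leave and
return") look converged.  `diagnose_convergence()` makes that reading
quantitative, with declared conventions:

* frames are binarised as similar at a cutoff of 0.2 nm C&alpha; RMSD
  (a package convention — the visual reading has no published cutoff);
* the frame range is split at the boundary maximising the fraction of
  similar pairs inside the two blocks, ties resolved to the earliest
  boundary so an A&rarr;B&rarr;A excursion keeps the early block
  minimal;
* `irreversible_transition` requires a cross-block similarity fraction
  below 0.05 *and* no late frame within the cutoff of any early-block
  frame; one or more returning frames give `leave_and_return`;
* a matrix in which no frame ever leaves the early neighbourhood —
  including the degenerate all-similar matrix — is `undetermined`:
  nothing was left, so "return" is not evidence.

## Ligand analyses

**Pose clustering.** The Gromos algorithm: the frame with the most
neighbours within the RMSD cutoff becomes a cluster centre, the
cluster is removed, and the step repeats.  The clustered quantity is
the ligand-atom RMSD after superposing each frame pair on the protein
backbone, so poses are defined in the receptor frame.  The default
cutoff is 0.2 nm, the conventional ligand-pose value.  Neighbour-count
ties promote the lower frame index, making runs reproducible.
Populations are reported over *all* clusters (they sum to 100%);
mapping clusters onto named reference poses is a separate, optional
step (`map_poses_to_references()`), because published pose tables
often list only a named subset.

**Flipping angle.** Ligand reorientation is measured as
arccos(&mu;<sub>&tau;</sub> &middot; &mu;<sub>&iota;</sub>), where
&mu; is a unit vector fixed in the ligand's bicyclic ring plane.  The
package defines &mu; as the vector from the centroid of the
six-membered ring to the centroid of the five-membered ring (atom
names configurable); this is deterministic, lies in the ring plane,
and is stable against coordinate jitter.  The angle at the reference
frame is exactly zero.

**Centre-of-mass cloud.** Each frame is aligned to the reference frame
on the backbone; the mass-weighted ligand centroid is collected in
that common frame.  Per-axis spreads are population standard
deviations (divide by n), so a symmetric two-point oscillation of
amplitude d has spread exactly d — convenient for closed-form checks.

**Cavity hydration.** The binding cavity is an axis-aligned bounding
box of user-specified binding-site residues, padded by 0.15 nm by
default (the defining-residue lists published with such analyses do
not include a padding; the default is configurable).  The box is
computed once on a reference or average structure and then held fixed
so counts are comparable across frames.  A water counts if its oxygen
lies inside the box, bounds inclusive.

## Membrane analyses

**Density profile and thickness.** The phosphate number-density
profile along z is measured from the instantaneous phosphate midplane,
so it is invariant under rigid z-translation.  Thickness is the
distance between the density-weighted mean z of the two leaflets
(leaflet = sign of z); the peak-to-peak distance is also reported.  A
profile with all mass on one side raises "no bilayer detected".

**Area per lipid.** A re-implementation of the grid method used for
protein-containing bilayers: each leaflet's plane is covered by an
n&times;n grid (default 100&times;100) and every cell is assigned to
the laterally nearest reference atom — one phosphorus per lipid,
competing with protein heavy atoms lying within &plusmn;0.5 nm of the
leaflet's phosphate plane — under the xy minimum-image metric.  Cell
areas are conserved by construction: per leaflet, lipid areas plus
protein-assigned area equal the lateral box area exactly, which the
tests assert to 1e-12.

**PN tilt.** The PN vector runs from a lipid's phosphorus to its
headgroup nitrogen; the tilt &Phi;<sub>PN</sub> is its angle to the
bilayer normal, with lower-leaflet lipids measured against the inward
normal so the distribution is leaflet-symmetric.  P and N atoms must
pair one-to-one by residue id; anything else is an error.

**Hydrogen bonds.** Donors and acceptors are declared per residue type
(a YAML-able table), never perceived from geometry.  The geometric
criterion is donor–acceptor distance &le; 0.35 nm and
H–donor–acceptor angle &le; 30&deg; — the convention of the common MD
analysis suites, since the published occupancy definitions rarely
state one.  Occupancies divide the mean bond count per frame by the
acceptor-oxygen count of the class's lipid side (protein–lipid,
lipid–lipid, lipid–solvent), a choice documented here because the
phrase "total number of acceptor oxygen atoms" is ambiguous across the
literature; with this normalisation a constructed frame with 5
lipid–lipid bonds and 20 lipid acceptor oxygens scores exactly 0.25.

**Diffusion.** Molecules are classified `proximal` if any of their
atoms comes within 0.35 nm of the protein in at least one analysed
frame ("ever" semantics; a per-frame mode is exposed for
sensitivity analysis).  Lateral MSD is averaged over molecules and all
time origins, after removing periodic jumps by mapping consecutive
displacements to their minimum image (valid while per-frame motion
stays below half the box — the generator enforces this).  MSD is
averaged first and fitted once, rather than fitting per molecule and
averaging: with few proximal molecules the per-molecule fits are
noise-dominated.  The fit window defaults to 10–50% of the maximum
lag, excluding the short-lag ballistic/noise regime and the poorly
sampled long-lag tail.  D = slope/4 (two dimensions), converted with
the exact chain 1 nm&sup2; = 1e-14 cm&sup2;, 1 ps = 1e-12 s, i.e.
1 nm&sup2;/ps = 1e-2 cm&sup2;/s, which is unit-tested as a constant.
A negative slope is reported with a warning flag rather than clamped.

## Helicity timeline

Secondary structure on C&alpha;-only models uses a geometric
criterion: residue i satisfies the &alpha;-helix signature when
d(C&alpha;<sub>i</sub>, C&alpha;<sub>i+4</sub>) &isin; [0.50, 0.65] nm,
and runs of at least three consecutive satisfying windows are labelled
helix.  States are defined for residues 3..N-2 (window edges are
coil), and consecutive-C&alpha; distances above 0.45 nm are chain
breaks that force the flanking residues to coil with a warning.  This
deliberately replaces a full hydrogen-bond-energy secondary-structure
assignment: the scientific claim being tested on synthetic traces is a
helix&rarr;coil transition, which the distance signature detects, and
C&alpha;-only fixtures carry no backbone hydrogens.  An ideal helix
(rise 0.15 nm, 100&deg;/residue, radius 0.23 nm) scores 100% helix in
its interior; an extended chain scores 0%.

## The synthetic generator and what it does (not) emulate

Because the trajectories behind the published analyses of this kind
are rarely deposited, `memtraj` ships a deterministic generator whose
parameters *are* the study conditions, so every analysis stage can be
validated by parameter recovery:

* `make_bilayer()` — two leaflets of pseudo-lipids (P, N, acceptor-O
  and tail beads; an amine hydrogen for POPE; a hydroxyl bead for
  cholesterol) on a jittered lattice with lattice constant
  &radic;APL, so the true area per lipid is exact by construction
  (default 0.61 nm&sup2;, the pure-POPC value).  Phosphate leaflets
  sit at &plusmn;1.9 nm (thickness 3.8 nm).  Headgroup tilt is drawn
  from a wrapped normal about the leaflet normal with uniform azimuth
  (default 90&deg; mean, 36&deg; sd — pure-POPC headgroup statistics);
  the wrapped normal is used rather than a von Mises because the
  recovery checks are phrased in terms of its mean and sd, and for
  these spreads the two are practically indistinguishable.
* `make_brownian()` — rigid lateral random walks with per-axis
  increment variance 2&middot;D&middot;dt, wrapped into the box
  (defaults 5e-8 cm&sup2;/s protein-proximal, 8e-8 cm&sup2;/s free;
  dt = 20 ps).  With a pseudo-protein present, near-protein molecules
  are pulled into contact at the first frame so the proximal/free
  classification has a ground truth.
* `make_ligand_traj()` — per-frame poses drawn from a categorical
  mixture (default 92.4/3.8/3.8%, the dominant-pose regime of a
  cholesterol-rich membrane) or a Markov chain with the same
  stationary distribution; coordinates are the reference pose plus
  isotropic jitter, and the whole system receives a small rigid wobble
  so backbone alignment is genuinely exercised.  Jitter approaching
  half the minimum inter-pose RMSD is rejected: clusters would merge
  by construction.
* `make_helix_trace()` — ideal helix with optional programmed
  unfolding of a residue range into an extended continuation from a
  chosen frame onward.
* `place_waters()` — an exact number of waters inside a cavity box and
  a stated number outside.

Every operation draws from its own RNG stream derived from the master
seed plus an operation tag, so adding one generator call never
perturbs another, and identical configs give bit-identical systems.

The generator is deliberately *not* physical: there are no forces,
no excluded volume, no headgroup–tail correlations, and pose dwell
times are memoryless.  Passing the recovery suite therefore shows
that the estimators are unbiased and correctly scaled on data with
the assumed statistical structure — it does not validate force
fields, sampling adequacy, or any property of real membranes.

## Numerical choices and degenerate inputs

Arc-cosines are always taken of dot products clamped to [-1, 1].
Kabsch superposition rejects fewer than three points and collinear
configurations (the rotation about the line is unconstrained).
Empty atom selections are legal but warned about where they are a
plausible user intent (`select_atoms()`), and errors where the
analysis is meaningless without atoms.  The pose-clustering
tie-break (lowest frame index) and the first-maximum rule in the
convergence segmentation pin down otherwise arbitrary choices so
reruns are identical.  Population standard deviations (not sample)
are used for the centre-of-mass cloud so two-point closed forms are
exact.  Pipeline reports contain no timestamps; a rerun with the same
config and seed is byte-identical.

## Problem sizes

The shipped tests and the acceptance script run at desk scale, chosen
so the whole suite completes in well under a minute of CPU for the
unit tests plus a few tens of seconds for the recovery checks: 128
lipids and 400–500 frames for diffusion recovery (about 5&times;10^4
increment samples), ~1e4 headgroup vectors per tilt replicate
(10 replicates), 100&times;100 grids for the area per lipid, and
20–300-frame trajectories for clustering and convergence.  The
estimators themselves are O(N&sup2;) in frames for the pairwise
matrices and clustering, so real 0.8-&micro;s runs should use the
matrix stride and the tail-window options.

## Known limitations

Only orthorhombic boxes; leaflet assignment by sign of z (no
curvature or undulation handling); bonds and donor/acceptor tables
are declared, not perceived; the helicity criterion knows only
helix/coil; the XTC plug-in point requires a user-supplied backend;
and the convergence verdict is a heuristic formalisation of a visual
diagnostic — its cutoff (0.2 nm) and overlap threshold (0.05) are
package conventions, exposed as parameters.
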
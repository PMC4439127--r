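Package: memtraj
Title: Membrane-Protein Molecular Dynamics Trajectory Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Analysis battery for molecular dynamics trajectories of
    membrane-embedded receptors: Kabsch superposition, RMSD/RMSF and
    all-to-all RMSD matrices with a quantitative convergence diagnosis,
    Gromos conformational clustering of ligand binding poses with
    populations, ligand mobility measures (orientational flipping angle,
    centre-of-mass cloud), binding-cavity hydration counts, lipid bilayer
    structure (phosphate density profile and thickness, grid-based area
    per lipid, headgroup PN tilt distributions, geometric hydrogen-bond
    occupancies) and Einstein-relation lateral diffusion with
    protein-proximity classification.  Includes fixed-column PDB and GRO
    readers/writers, a deterministic synthetic-system generator with
    known ground truth for every analysis stage, and a pipeline
    orchestrator emitting machine-readable reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d,
    optparse
Config/testthat/edition: 3
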
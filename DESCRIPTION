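Package: btkloop
Title: Trajectory Analytics for Kinase Activation-Loop Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tidy analysis of molecular-dynamics trajectories of protein
    kinase domains, built around the observables used to characterise
    activation-loop (A-loop) remodelling in Bruton's tyrosine kinase (BTK):
    region-wise RMSD, per-residue RMSF and radius of gyration from Kabsch
    superposition; the beta6/beta7-to-DFG line angle and the DFG-to-ATP-site
    centroid distance; Shrake-Rupley solvent-accessible surface area;
    geometric hydrogen-bond and salt-bridge detection with per-bond survival
    (occupancy) statistics; and run-level wild-type versus mutant comparison
    by the unpaired two-tailed Student's t-test. Reads PDB and CHARMM/NAMD
    DCD trajectories, ships the BTK kinase-domain region definitions as a
    default, and includes a synthetic-trajectory generator that plants known
    per-residue fluctuations, bond-formation probabilities, rigid-body
    motions and angle series so every analysis stage is testable without
    cluster-scale simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    bio3d,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
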
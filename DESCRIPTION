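Package: porescope
Title: Pore Geometry, Ligand Pose and Free-Energy Analysis for Pentameric
    Ligand-Gated Ion Channels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Structural and trajectory analysis of pentameric ligand-gated ion
    channels, centred on the alpha1-beta2-gamma2 GABA-A receptor. Computes
    maximal inscribed-sphere pore radius profiles along the channel axis and
    minimal diameters at M2 prime positions, ligand stability (aligned RMSD
    traces with optional cropping, pore-axis displacement) and RMSD-cutoff
    pose clustering, residue-ligand contact-frequency fingerprints with
    replicate aggregation, pore hydration counts and upper-ECD spread, and
    1D permeation free-energy profiles by Boltzmann inversion with barrier
    extraction. A seeded synthetic-data generator produces ground-truthed
    pseudo-pentameric channels, trajectories and ion samples so every stage
    of the pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
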
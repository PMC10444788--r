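#!/usr/bin/env Rscript
# Ligand-stability analyses on the simulated trajectories: aligned RMSD
# traces (with the 60 -> 10 A crop preset for the unbinding runs), pore-axis
# displacement of the pore-blocking ligand, and QT pose clustering at the
# 1 A cutoff with up to 10 clusters, exporting the top-5 representatives.

suppressPackageStartupMessages(library(porescope))
dir.create("results/ligand", showWarnings = FALSE, recursive = TRUE)

block <- read_trajectory("results/simulated/pore_block.pdb")
lig <- select_atoms(block$topology, resid = "DHS", heavy = TRUE)
tr <- ligand_rmsd_trace(block, lig)
zt <- ligand_z_trace(block, lig)
write_result_csv(as.data.frame(tr), "results/ligand/block_rmsd.csv")
write_result_csv(as.data.frame(zt), "results/ligand/block_z.csv")
cat(sprintf("pore-block ligand: median rmsd %.2f A, final z drift %+.2f A\n",
            median(tr$rmsd), zt$dz[nrow(zt)]))

cl <- cluster_poses(block, lig, cutoff = 1.0, max_clusters = 10)
print(cl)
write_representatives(block, cl, "results/ligand/representatives.pdb",
                      top = 5)
jsonlite::write_json(list(populations = cl$populations,
                          representatives = cl$representatives,
                          cutoff = cl$cutoff),
                     "results/ligand/clusters.json", auto_unbox = TRUE,
                     digits = NA)

cp <- crop_preset_unbinding()
for (run in c("unbinding", "no_escape")) {
  traj <- read_trajectory(sprintf("results/simulated/%s.pdb", run))
  lg <- select_atoms(traj$topology, resid = "DHS", heavy = TRUE)
  t2 <- ligand_rmsd_trace(traj, lg, crop_threshold = cp$crop_threshold,
                          crop_value = cp$crop_value)
  write_result_csv(as.data.frame(t2),
                   sprintf("results/ligand/%s_rmsd.csv", run))
  dens <- trace_density(t2$rmsd)
  write_result_csv(dens, sprintf("results/ligand/%s_rmsd_density.csv", run))
  cat(sprintf("%-10s: %d/%d frames cropped (raw rmsd > %g A)\n", run,
              sum(t2$cropped), nrow(t2), cp$crop_threshold))
}
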
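#!/usr/bin/env Rscript
# Generate the synthetic study systems used by the downstream analyses:
# four pseudo-pentameric channels whose calibrated pore geometry emulates
# the modulated receptor states, a pore-blocked trajectory with programmed
# contacts/hydration/breathing, and agonist unbinding / no-unbinding runs.
# Everything is seeded and written as plain multi-(model) PDB plus the
# ground-truth tables, so later steps can be checked against what was
# programmed.

suppressPackageStartupMessages(library(porescope))
seed <- 1L
dir.create("results/simulated", showWarnings = FALSE, recursive = TRUE)

for (st in c("gaba", "gaba_allo", "etomidate", "propofol")) {
  ch <- synthetic_state_channel(st, seed = seed)
  write_structure(ch$structure, sprintf("results/simulated/channel_%s.pdb", st))
  write_result_csv(ch$truth, sprintf("results/simulated/truth_profile_%s.csv", st))
  cat(sprintf("%-10s: %d atoms, programmed 9' diameter %.1f A\n", st,
              nrow(ch$structure),
              ch$control_diameters$diameter[ch$control_diameters$prime == 9]))
}

spec <- synthetic_spec(seed = seed, n_frames = 40,
                       ligand_jitter_sigma = 0.15,
                       contact_schedule = c("alpha:-2" = 0.95, "beta:-2" = 0.95,
                                            "gamma:-2" = 0.9, "alpha:2" = 0.85,
                                            "beta:2" = 0.8, "gamma:2" = 0.8,
                                            "beta:9" = 0.35),
                       water_plan = list(inside = c(3L, 4L, 5L, 4L), outside = 4L),
                       breathing = seq(1, 0.95, length.out = 40))
fx <- make_toy_trajectory(spec)
write_trajectory(fx$trajectory, "results/simulated/pore_block.pdb")
write_result_csv(fx$truth$contacts, "results/simulated/truth_contacts.csv")
write_result_csv(fx$truth$hydration, "results/simulated/truth_hydration.csv")
write_result_csv(fx$truth$spread, "results/simulated/truth_spread.csv")
cat(sprintf("pore-block trajectory: %d frames, %d atoms\n",
            n_frames(fx$trajectory), nrow(fx$trajectory$topology)))

ub <- make_unbinding_trajectory(synthetic_spec(seed = seed, n_frames = 200,
                                               escape_frame = 100,
                                               ligand_jitter_sigma = 0.1))
write_trajectory(ub$trajectory, "results/simulated/unbinding.pdb")
nb <- make_unbinding_trajectory(synthetic_spec(seed = seed + 1, n_frames = 200,
                                               ligand_jitter_sigma = 0.1))
write_trajectory(nb$trajectory, "results/simulated/no_escape.pdb")
cat("unbinding run escapes at frame 100; control run never leaves\n")
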
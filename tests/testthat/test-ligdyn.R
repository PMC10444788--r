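make_static_fixture <- function(n_frames = 10, drift = 0, jitter = 0,
                                seed = 1) {
  make_toy_trajectory(synthetic_spec(seed = seed, n_frames = n_frames,
                                     ligand_drift = drift,
                                     ligand_jitter_sigma = jitter))
}

test_that("a static ligand gives an all-zero rmsd and z trace", {
  fx <- make_static_fixture()
  traj <- fx$trajectory
  lig <- select_atoms(traj$topology, resid = "DHS", heavy = TRUE)
  tr <- ligand_rmsd_trace(traj, lig)
  zt <- ligand_z_trace(traj, lig)
  expect_equal(tr$rmsd, rep(0, 10), tolerance = 1e-9)
  expect_equal(zt$dz, rep(0, 10), tolerance = 1e-9)
  expect_equal(zt$dz[1], 0)
})

test_that("a pure translation in one frame reads as exactly that rmsd", {
  fx <- make_static_fixture()
  traj <- fx$trajectory
  lig <- select_atoms(traj$topology, resid = "DHS", heavy = TRUE)
  k <- 6
  traj$coords[lig, 1, k] <- traj$coords[lig, 1, k] + 3
  traj$coords[lig, 2, k] <- traj$coords[lig, 2, k] + 4
  tr <- ligand_rmsd_trace(traj, lig)
  expect_equal(tr$rmsd[k], 5.0, tolerance = 1e-9)
  expect_equal(tr$rmsd[-k], rep(0, 9), tolerance = 1e-9)
})

test_that("the crop preset stores 10 for raw excursions beyond 60", {
  fx <- make_unbinding_trajectory(synthetic_spec(n_frames = 20,
                                                 escape_frame = 13,
                                                 ligand_jitter_sigma = 0.05))
  traj <- fx$trajectory
  lig <- select_atoms(traj$topology, resid = "DHS", heavy = TRUE)
  cp <- crop_preset_unbinding()
  tr <- ligand_rmsd_trace(traj, lig, crop_threshold = cp$crop_threshold,
                          crop_value = cp$crop_value)
  expect_true(all(tr$raw_rmsd[tr$cropped] > 60))
  expect_equal(tr$rmsd[tr$cropped], rep(10, sum(tr$cropped)))
  expect_true(all(which(tr$cropped) >= 13))
  expect_true(any(tr$cropped))
  # no-escape control: nothing is ever cropped
  fx0 <- make_unbinding_trajectory(synthetic_spec(n_frames = 20,
                                                  ligand_jitter_sigma = 0.05))
  tr0 <- ligand_rmsd_trace(fx0$trajectory, lig,
                           crop_threshold = 60, crop_value = 10)
  expect_false(any(tr0$cropped))
})

test_that("programmed axial drift accumulates linearly in the z trace", {
  fx <- make_static_fixture(n_frames = 51, drift = 0.1)
  traj <- fx$trajectory
  lig <- select_atoms(traj$topology, resid = "DHS", heavy = TRUE)
  zt <- ligand_z_trace(traj, lig)
  expect_equal(zt$dz[51], 5.0, tolerance = 1e-6)
  expect_equal(zt$dz, fx$truth$z$dz, tolerance = 1e-9)
})

test_that("a sulfate-down pose programmed to sink shows a negative slope", {
  fx <- make_static_fixture(n_frames = 40, drift = -0.08, jitter = 0.15,
                            seed = 21)
  traj <- fx$trajectory
  lig <- select_atoms(traj$topology, resid = "DHS", heavy = TRUE)
  zt <- ligand_z_trace(traj, lig)
  slope <- coef(lm(dz ~ frame, data = zt))[["frame"]]
  expect_lt(slope, 0)
})

test_that("rmsd trace is invariant under a global rigid motion of all frames", {
  fx <- make_static_fixture(n_frames = 8, jitter = 0.4, seed = 3)
  traj <- fx$trajectory
  lig <- select_atoms(traj$topology, resid = "DHS", heavy = TRUE)
  t0 <- ligand_rmsd_trace(traj, lig)
  set.seed(12)
  tr <- rigid_transform(porescope:::random_rotation(), c(5, -3, 9))
  moved <- transform_trajectory(traj, tr)
  # reference frame comes from the (also transformed) first frame
  t1 <- ligand_rmsd_trace(moved, lig)
  expect_equal(t1$rmsd, t0$rmsd, tolerance = 1e-6)
})

test_that("identical frames collapse into a single cluster", {
  fx <- make_static_fixture(n_frames = 6)
  traj <- fx$trajectory
  lig <- select_atoms(traj$topology, resid = "DHS", heavy = TRUE)
  cl <- cluster_poses(traj, lig)
  expect_equal(length(cl$populations), 1L)
  expect_equal(cl$populations, 6L)
  expect_equal(unique(cl$labels), 1L)
  expect_error(cluster_poses(traj, lig, cutoff = 0), "parameter error")
})

test_that("two separated pose groups are recovered exactly", {
  fx <- make_static_fixture(n_frames = 12, jitter = 0.08, seed = 5)
  traj <- fx$trajectory
  lig <- select_atoms(traj$topology, resid = "DHS", heavy = TRUE)
  group2 <- seq(7, 12)
  traj$coords[lig, 1, group2] <- traj$coords[lig, 1, group2] + 5
  cl <- cluster_poses(traj, lig, cutoff = 1)
  expect_equal(length(cl$populations), 2L)
  expect_equal(sort(unique(cl$labels[group2])), unique(cl$labels[group2]))
  expect_true(all(cl$labels[group2] == cl$labels[7]))
  expect_true(all(cl$labels[-group2] == cl$labels[1]))
  expect_false(cl$labels[1] == cl$labels[7])
  # matches the greedy QT oracle on the same distance matrix
  D <- ligand_rmsd_matrix(traj, lig)
  expect_equal(cl$labels, oracle_qt_clusters(D, 1, 10))
})

test_that("cluster populations are non-increasing and noise is labelled 0", {
  fx <- make_static_fixture(n_frames = 30, jitter = 0.6, seed = 8)
  traj <- fx$trajectory
  lig <- select_atoms(traj$topology, resid = "DHS", heavy = TRUE)
  cl <- cluster_poses(traj, lig, cutoff = 0.8, max_clusters = 3)
  expect_true(all(diff(cl$populations) <= 0))
  expect_equal(sum(cl$populations) + sum(cl$labels == 0L), 30L)
  # representatives belong to their own cluster
  for (k in seq_along(cl$representatives))
    expect_equal(cl$labels[cl$representatives[k]], k)
})

test_that("clustering is stable under frame permutation", {
  fx <- make_static_fixture(n_frames = 16, jitter = 0.5, seed = 13)
  traj <- fx$trajectory
  lig <- select_atoms(traj$topology, resid = "DHS", heavy = TRUE)
  cl0 <- cluster_poses(traj, lig, cutoff = 1.2, max_clusters = 4,
                       reference = traj$topology)
  set.seed(4)
  perm <- sample(16)
  shuf <- as_trajectory(traj$topology, traj$coords[, , perm],
                        frame_interval = traj$frame_interval)
  cl1 <- cluster_poses(shuf, lig, cutoff = 1.2, max_clusters = 4,
                       reference = traj$topology)
  # unshuffle and compare as partitions (labels may be renumbered)
  lab1 <- integer(16)
  lab1[perm] <- cl1$labels
  part <- function(l) unname(split(seq_along(l), l))
  expect_setequal(lapply(part(cl0$labels), sort), lapply(part(lab1), sort))
})

test_that("top-5 representative export writes a 5-model PDB", {
  fx <- make_static_fixture(n_frames = 40, jitter = 1.2, seed = 2)
  traj <- fx$trajectory
  lig <- select_atoms(traj$topology, resid = "DHS", heavy = TRUE)
  cl <- cluster_poses(traj, lig, cutoff = 0.5, max_clusters = 10)
  expect_gte(length(cl$populations), 5L)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_representatives(traj, cl, f, top = 5)
  back <- read_trajectory(f)
  expect_equal(n_frames(back), 5L)
})
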
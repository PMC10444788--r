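test_that("a ligand far from every residue yields all-zero frequencies", {
  fx <- make_toy_trajectory(synthetic_spec(n_frames = 5))
  traj <- fx$trajectory
  lig <- select_atoms(traj$topology, resid = "DHS", heavy = TRUE)
  ct <- contact_frequencies(traj, lig)
  expect_true(all(ct$frequency == 0))
  expect_equal(attr(ct, "frames_counted"), 5L)
  expect_equal(attr(ct, "cutoff"), 4.5)
})

test_that("a programmed contact schedule is recovered exactly", {
  spec <- synthetic_spec(n_frames = 10,
                         contact_schedule = c("alpha:2" = 1.0,
                                              "beta:9" = 0.3))
  fx <- make_toy_trajectory(spec)
  traj <- fx$trajectory
  lig <- select_atoms(traj$topology, resid = "DHS", heavy = TRUE)
  ct <- contact_frequencies(traj, lig)
  for (i in seq_len(nrow(fx$truth$contacts))) {
    row <- fx$truth$contacts[i, ]
    got <- ct$frequency[ct$chain == row$chain & ct$resno == row$resno]
    expect_equal(got, row$frequency)
    # cross-check against the per-frame brute-force distance scan
    expect_equal(got, oracle_contact_freq(traj, lig, row$chain, row$resno))
  }
  # everything unscheduled stays at zero in this fixture
  key <- paste(ct$chain, ct$resno)
  sched <- paste(fx$truth$contacts$chain, fx$truth$contacts$resno)
  expect_true(all(ct$frequency[!(key %in% sched)] == 0))
})

test_that("a residue within cutoff in exactly 7 of 10 frames scores 0.70", {
  spec <- synthetic_spec(n_frames = 10,
                         contact_schedule = c("gamma:5" = 0.7))
  fx <- make_toy_trajectory(spec)
  traj <- fx$trajectory
  lig <- select_atoms(traj$topology, resid = "DHS", heavy = TRUE)
  ct <- contact_frequencies(traj, lig)
  row <- fx$truth$contacts[1, ]
  expect_equal(ct$frequency[ct$chain == row$chain & ct$resno == row$resno],
               0.70)
})

test_that("frequencies are invariant under frame reordering and monotone in cutoff", {
  spec <- synthetic_spec(n_frames = 8, contact_schedule = c("beta:2" = 0.5))
  traj <- make_toy_trajectory(spec)$trajectory
  lig <- select_atoms(traj$topology, resid = "DHS", heavy = TRUE)
  ct <- contact_frequencies(traj, lig)
  set.seed(6)
  perm <- sample(8)
  shuf <- as_trajectory(traj$topology, traj$coords[, , perm],
                        frame_interval = traj$frame_interval)
  ct_shuf <- contact_frequencies(shuf, lig)
  expect_equal(ct$frequency, ct_shuf$frequency)
  wider <- contact_frequencies(traj, lig, cutoff = 7.5)
  expect_true(all(wider$frequency >= ct$frequency))
})

test_that("replicate aggregation computes sample mean and sd with zero-fill", {
  base <- make_toy_trajectory(synthetic_spec(n_frames = 10,
                                             contact_schedule = c("alpha:2" = 0.4)))
  other <- make_toy_trajectory(synthetic_spec(n_frames = 10, seed = 2,
                                              contact_schedule = c("alpha:2" = 0.6)))
  lig1 <- select_atoms(base$trajectory$topology, resid = "DHS", heavy = TRUE)
  t1 <- contact_frequencies(base$trajectory, lig1)
  t2 <- contact_frequencies(other$trajectory, lig1)
  sm <- summarize_replicates(list(t1, t2))
  row <- base$truth$contacts[1, ]
  m <- sm[sm$chain == row$chain & sm$resno == row$resno, ]
  expect_equal(m$mean, 0.5)
  expect_equal(m$sd, 0.141421, tolerance = 1e-5)
  expect_equal(unique(sm$n), 2L)
  expect_error(summarize_replicates(list(t1)), "degenerate")
  # k identical copies reproduce the table with sd exactly 0
  sm3 <- summarize_replicates(list(t1, t1, t1))
  expect_equal(sm3$mean[order(sm3$chain, sm3$resno)],
               t1$frequency[order(t1$chain, t1$resno)])
  expect_true(all(sm3$sd == 0))
})

test_that("the >= 50 percent rule is inclusive and sorted", {
  t1 <- structure(data.frame(chain = "A", resno = 1:3, resid = "GLY",
                             frequency = c(0.49, 0.50, 0.51),
                             n_contact_frames = c(49L, 50L, 51L)),
                  cutoff = 4.5, frames_counted = 100L,
                  class = c("ContactTable", "data.frame"))
  t2 <- t1
  sm <- summarize_replicates(list(t1, t2))
  fc <- frequent_contacts(sm)
  expect_equal(fc$resno, c(3L, 2L))  # sorted by mean desc, then resno
  expect_equal(fc$mean, c(0.51, 0.50))
  # brute-force filter agrees
  expect_setequal(fc$resno, sm$resno[sm$mean >= 0.5])
  # empty input stays empty
  expect_equal(nrow(frequent_contacts(sm, threshold = 0.99)), 0L)
})

test_that("a pore-bound ligand touches the -2' and 2' rings of all chains", {
  # schedule high-frequency contacts at the inner-pore rings across classes,
  # mirroring a sulfated-steroid block pose
  spec <- synthetic_spec(n_frames = 10,
                         contact_schedule = c("alpha:-2" = 0.9,
                                              "beta:-2" = 0.9,
                                              "gamma:-2" = 0.9,
                                              "alpha:2" = 0.8,
                                              "beta:2" = 0.8,
                                              "gamma:2" = 0.8))
  fx <- make_toy_trajectory(spec)
  traj <- fx$trajectory
  lig <- select_atoms(traj$topology, resid = "DHS", heavy = TRUE)
  ct <- contact_frequencies(traj, lig)
  sm <- summarize_replicates(list(ct, ct))
  fc <- frequent_contacts(annotate_primes(sm, build_prime_map(
    traj$topology, subunit_map(spec$chains))))
  expect_setequal(unique(fc$prime), c(-2L, 2L))
  expect_equal(nrow(fc), 10L)  # five chains x two rings
})
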
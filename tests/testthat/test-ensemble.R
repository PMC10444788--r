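test_that("a dry system returns an all-zero hydration trace with a warning", {
  fx <- make_toy_trajectory(synthetic_spec(n_frames = 4))
  traj <- fx$trajectory
  pm <- build_prime_map(traj$topology, subunit_map(fx$spec$chains))
  expect_warning(ht <- hydration_count(traj, prime_map = pm), "no waters")
  expect_equal(ht$count, rep(0L, 4))
})

test_that("programmed gate-water counts are recovered exactly", {
  spec <- synthetic_spec(n_frames = 6,
                         water_plan = list(inside = c(3L, 5L),
                                           outside = 4L))
  fx <- make_toy_trajectory(spec)
  traj <- fx$trajectory
  pm <- build_prime_map(traj$topology, subunit_map(spec$chains))
  ht <- hydration_count(traj, prime_map = pm)
  expect_equal(ht$count, rep(c(3L, 5L), 3))
  expect_equal(ht$count, fx$truth$hydration$count)
  # brute-force all-pairs counting agrees frame by frame
  gate <- select_prime_ring(traj$topology, pm, 9L)
  for (i in seq_len(6))
    expect_equal(ht$count[i], oracle_water_count(traj, i, gate))
})

test_that("waters just inside vs outside the cutoff are separated exactly", {
  spec <- synthetic_spec(n_frames = 2,
                         water_plan = list(inside = 4L, outside = 7L))
  fx <- make_toy_trajectory(spec)
  traj <- fx$trajectory
  pm <- build_prime_map(traj$topology, subunit_map(spec$chains))
  # tighten the cutoff below the 2.5 A placement: counts collapse to zero
  expect_equal(hydration_count(traj, prime_map = pm, cutoff = 2.4)$count,
               rep(0L, 2))
  expect_equal(hydration_count(traj, prime_map = pm, cutoff = 3.0)$count,
               rep(4L, 2))
})

test_that("a wider pore with a fuller water plan shifts the count distribution", {
  narrow <- make_toy_trajectory(synthetic_spec(
    n_frames = 20, water_plan = list(inside = c(0L, 1L, 0L, 2L), outside = 3L)))
  wide <- make_toy_trajectory(synthetic_spec(
    n_frames = 20, pore_radius = function(z) rep(6, length(z)),
    water_plan = list(inside = c(4L, 6L, 5L, 7L), outside = 3L)))
  pmn <- build_prime_map(narrow$trajectory$topology,
                         subunit_map(narrow$spec$chains))
  pmw <- build_prime_map(wide$trajectory$topology,
                         subunit_map(wide$spec$chains))
  hn <- hydration_count(narrow$trajectory, prime_map = pmn)
  hw <- hydration_count(wide$trajectory, prime_map = pmw)
  expect_gt(mean(hw$count), mean(hn$count))
})

test_that("a static trajectory has zero COM displacement and constant spread", {
  fx <- make_toy_trajectory(synthetic_spec(n_frames = 5))
  er <- ecd_ranges(list(alpha = rbind(c(1, 8)), beta = rbind(c(1, 8)),
                        gamma = rbind(c(1, 8))))
  sm <- subunit_map(fx$spec$chains)
  disp <- ecd_spread(fx$trajectory, er, sm, mode = "com_displacement")
  rad <- ecd_spread(fx$trajectory, er, sm, mode = "radial_spread")
  expect_equal(disp$value, rep(0, 5), tolerance = 1e-9)
  expect_equal(rad$value, rep(rad$value[1], 5), tolerance = 1e-9)
})

test_that("radial breathing scales the spread exactly", {
  breathing <- c(1, 1.1, 0.95, 1.05, 1)
  fx <- make_toy_trajectory(synthetic_spec(n_frames = 5,
                                           breathing = breathing))
  er <- ecd_ranges(list(alpha = rbind(c(1, 8)), beta = rbind(c(1, 8)),
                        gamma = rbind(c(1, 8))))
  sm <- subunit_map(fx$spec$chains)
  rad <- ecd_spread(fx$trajectory, er, sm, mode = "radial_spread")
  expect_equal(rad$value / rad$value[1], breathing, tolerance = 1e-6)
  expect_equal(rad$value, fx$truth$spread$value, tolerance = 1e-6)
  # contraction lowers the spread
  expect_lt(rad$value[3], rad$value[1])
  # COM-displacement mode matches its own ground truth
  disp <- ecd_spread(fx$trajectory, er, sm, mode = "com_displacement")
  expect_equal(disp$value, fx$truth$com_displacement$value, tolerance = 1e-4)
})

test_that("spread is invariant under global rigid motion of every frame", {
  fx <- make_toy_trajectory(synthetic_spec(n_frames = 4,
                                           breathing = c(1, 1.08, 0.97, 1.02)))
  er <- ecd_ranges(list(alpha = rbind(c(1, 8)), beta = rbind(c(1, 8)),
                        gamma = rbind(c(1, 8))))
  sm <- subunit_map(fx$spec$chains)
  r0 <- ecd_spread(fx$trajectory, er, sm)
  moved <- fx$trajectory
  set.seed(19)
  for (i in seq_len(4)) {
    tr <- rigid_transform(porescope:::random_rotation(), rnorm(3, sd = 8))
    moved$coords[, , i] <- apply_transform(moved$coords[, , i], tr)
  }
  r1 <- ecd_spread(moved, er, sm)
  expect_equal(r1$value, r0$value, tolerance = 1e-6)
})

test_that("unit-mass and mass-weighted spreads differ by under 2 percent", {
  fx <- make_toy_trajectory(synthetic_spec(n_frames = 3,
                                           breathing = c(1, 1.1, 1)))
  er <- ecd_ranges(list(alpha = rbind(c(1, 8)), beta = rbind(c(1, 8)),
                        gamma = rbind(c(1, 8))))
  sm <- subunit_map(fx$spec$chains)
  a <- ecd_spread(fx$trajectory, er, sm, mass_weighted = TRUE)
  b <- ecd_spread(fx$trajectory, er, sm, mass_weighted = FALSE)
  expect_lt(max(abs(a$value - b$value) / a$value), 0.02)
})

test_that("a subunit without resolved ECD atoms is an error naming the chain", {
  fx <- make_toy_trajectory(synthetic_spec(n_frames = 2))
  er <- ecd_ranges(list(alpha = rbind(c(900, 950)), beta = rbind(c(1, 8)),
                        gamma = rbind(c(1, 8))))
  sm <- subunit_map(fx$spec$chains)
  expect_error(ecd_spread(fx$trajectory, er, sm), "chain A")
})

test_that("the shipped receptor config carries the published ECD intervals", {
  cfg <- gabaa_config()
  expect_equal(cfg$ecd_ranges$beta[1, ], c(7, 43))
  expect_equal(cfg$ecd_ranges$alpha[5, ], c(200, 213))
  expect_equal(cfg$ecd_ranges$gamma[3, ], c(119, 145))
  expect_equal(unname(cfg$anchors["alpha"] - 7L), 257L)  # 2' valine
  expect_equal(unname(cfg$anchors["beta"] - 7L), 252L)   # 2' alanine
})
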
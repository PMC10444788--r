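test_that("a minimal one-atom PDB parses to the written record", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(paste0("ATOM      1  CA  ALA A   7      11.104  -2.500",
                      "   3.250  1.00  0.00           C"),
               "END"), f)
  s <- read_structure(f)
  expect_s3_class(s, "Structure")
  expect_equal(nrow(s), 1L)
  expect_equal(s$chain, "A")
  expect_equal(s$resno, 7L)
  expect_equal(s$elety, "CA")
  expect_equal(c(s$x, s$y, s$z), c(11.104, -2.5, 3.25))
})

test_that("structure write/read round-trips atom identity and coordinates", {
  ch <- make_toy_channel(synthetic_spec(pore_radius = function(z)
    rep(3, length(z))))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(ch$structure, f)
  back <- read_structure(f)
  expect_equal(nrow(back), nrow(ch$structure))
  expect_equal(back$chain, ch$structure$chain)
  expect_equal(back$resno, ch$structure$resno)
  expect_equal(back$elety, ch$structure$elety)
  expect_equal(coords(back), coords(ch$structure), tolerance = 2e-3)
  expect_lt(max(abs(coords(back) - coords(ch$structure))), 1e-3 + 1e-9)
})

test_that("altloc policy keeps highest occupancy, ties alphabetically", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA ALEU A   9       1.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BLEU A   9       2.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CB ALEU A   9       3.000   0.000   0.000  0.50  0.00           C",
    "ATOM      4  CB BLEU A   9       4.000   0.000   0.000  0.50  0.00           C",
    "END"), f)
  s <- read_structure(f)
  expect_equal(nrow(s), 2L)
  expect_equal(s$x[s$elety == "CA"], 2.0)  # higher occupancy wins
  expect_equal(s$x[s$elety == "CB"], 3.0)  # tie broken alphabetically (A)
})

test_that("trajectory round-trip preserves frames, order and interval default", {
  spec <- synthetic_spec(n_frames = 3, ligand_drift = 0.5)
  traj <- make_toy_trajectory(spec)$trajectory
  f <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory(traj, f)
  back <- read_trajectory(f)
  expect_equal(n_frames(back), 3L)
  expect_equal(back$frame_interval, 0.4)
  for (i in 1:3)
    expect_lt(max(abs(frame_coords(back, i) - frame_coords(traj, i))), 1e-3 + 1e-9)
  # programmed per-frame ligand drift survives the round trip
  lig <- select_atoms(back$topology, resid = "DHS")
  com_z <- sapply(1:3, function(i) mean(frame_coords(back, i)[lig, 3]))
  expect_equal(com_z - com_z[1], 0.5 * (0:2), tolerance = 1e-3)
})

test_that("models disagreeing on atom count raise a topology error", {
  f <- withr::local_tempfile(fileext = ".pdb")
  atom <- function(i, x) sprintf(
    "ATOM  %5d  CA  GLY A%4d    %8.3f   0.000   0.000  1.00  0.00           C",
    i, i, x)
  writeLines(c("MODEL        1", atom(1, 0), atom(2, 1), atom(3, 2), "ENDMDL",
               "MODEL        2", atom(1, 0), atom(2, 1), "ENDMDL", "END"), f)
  expect_error(read_trajectory(f), "topology|atom")
})

test_that("Kabsch superposition recovers planted rigid motions exactly", {
  set.seed(7)
  for (rep in 1:5) {
    P <- matrix(rnorm(30, sd = 5), 10, 3)
    R <- porescope:::random_rotation()
    t <- rnorm(3, sd = 10)
    Q <- sweep(P %*% t(R), 2, -t)
    fit <- superpose(P, Q)
    expect_lt(fit$rmsd, 1e-6)
    expect_equal(fit$transform$rotation, R, tolerance = 1e-6)
  }
  # identical structures: identity transform, zero rmsd
  fit0 <- superpose(P, P)
  expect_lt(fit0$rmsd, 1e-9)
  expect_equal(fit0$transform$rotation, diag(3), tolerance = 1e-9)
})

test_that("superpose rmsd equals brute-force minimisation over rotations", {
  set.seed(11)
  for (rep in 1:3) {
    P <- matrix(rnorm(30, sd = 3), 10, 3)
    Q <- matrix(rnorm(30, sd = 3), 10, 3)
    fit <- superpose(P, Q)
    expect_equal(fit$rmsd, oracle_superpose_rmsd(P, Q), tolerance = 1e-6)
  }
})

test_that("superpose rmsd is symmetric and degenerate input errors", {
  set.seed(3)
  P <- matrix(rnorm(24, sd = 4), 8, 3)
  Q <- matrix(rnorm(24, sd = 4), 8, 3)
  expect_equal(superpose(P, Q)$rmsd, superpose(Q, P)$rmsd, tolerance = 1e-9)
  expect_error(superpose(P[1:2, ], Q[1:2, ]), "3 paired atoms")
  line <- cbind(1:5, 0, 0)
  expect_error(superpose(line, line + 1), "collinear")
})

test_that("prime map arithmetic follows the anchor+offset rule", {
  ch <- make_toy_channel(synthetic_spec())
  sm <- subunit_map(c(A = "alpha", B = "beta", C = "alpha", D = "beta",
                      E = "gamma"))
  pm <- build_prime_map(ch$structure, sm)
  # alpha anchor 264: prime 2 -> V257; prime 9 -> the anchor itself
  a <- pm[pm$class == "alpha" & pm$chain == "A", ]
  expect_equal(a$resno[a$prime == 2], 257L)
  expect_equal(a$resno[a$prime == 9], 264L)
  # beta anchor 259: prime 2 -> A252, prime -2 -> 248
  b <- pm[pm$class == "beta" & pm$chain == "B", ]
  expect_equal(b$resno[b$prime == 2], 252L)
  expect_equal(b$resno[b$prime == -2], 248L)
  # difference property over all pairs
  for (ch_id in unique(pm$chain)) {
    sub <- pm[pm$chain == ch_id, ]
    expect_true(all(outer(sub$resno, sub$resno, "-") ==
                      outer(sub$prime, sub$prime, "-")))
  }
  # the 2' residues carry the receptor identities used for inference
  expect_equal(unique(ch$structure$resid[ch$structure$chain == "A" &
                                           ch$structure$resno == 257]), "VAL")
  expect_equal(unique(ch$structure$resid[ch$structure$chain == "B" &
                                           ch$structure$resno == 252]), "ALA")
})

test_that("subunit map enforces pentamer composition and inference works", {
  expect_error(subunit_map(c(A = "alpha", B = "beta")), "5 chains")
  expect_error(subunit_map(c(A = "alpha", B = "alpha", C = "alpha",
                             D = "beta", E = "gamma")), "2 alpha")
  ch <- make_toy_channel(synthetic_spec())
  inferred <- infer_subunit_map(ch$structure)
  expect_equal(inferred$class[inferred$chain == "A"], "alpha")
  expect_equal(inferred$class[inferred$chain == "B"], "beta")
  expect_equal(inferred$class[inferred$chain == "E"], "gamma")
})

test_that("pore-axis alignment recovers planted rotations and is idempotent", {
  ch <- make_toy_channel(synthetic_spec(pore_radius = function(z)
    rep(3, length(z))))
  sm <- subunit_map(c(A = "alpha", B = "beta", C = "alpha", D = "beta",
                      E = "gamma"))
  pm <- build_prime_map(ch$structure, sm)
  al0 <- align_pore_axis(ch$structure, sm, pm)
  # a channel built along z: alignment is a pure translation
  expect_equal(al0$transform$rotation, diag(3), tolerance = 1e-6)
  set.seed(5)
  for (rep in 1:3) {
    R <- porescope:::random_rotation()
    rotated <- apply_transform(ch$structure,
                               rigid_transform(R, rnorm(3, sd = 20)))
    al <- align_pore_axis(rotated, sm, pm)
    # recovered axis within 0.5 degrees: rotation returns +z wall to +z wall
    zdir <- al$transform$rotation %*% R %*% c(0, 0, 1)
    ang <- acos(min(1, zdir[3])) * 180 / pi
    expect_lt(ang, 0.5)
    # idempotent: re-aligning moves coordinates by < 1e-6
    al2 <- align_pore_axis(al$structure, sm, pm)
    expect_lt(max(abs(coords(al2$structure) - coords(al$structure))), 1e-6)
  }
})

test_that("9' ring z-coordinates agree across chains after alignment", {
  ch <- synthetic_state_channel("gaba")
  sm <- subunit_map(ch$spec$chains)
  pm <- build_prime_map(ch$structure, sm)
  al <- align_pore_axis(ch$structure, sm, pm)
  z9 <- sapply(unique(pm$chain), function(cc) {
    rn <- pm$resno[pm$chain == cc & pm$prime == 9]
    idx <- select_atoms(al$structure, chain = cc, resno = rn)
    mean(al$structure$z[idx])
  })
  expect_lt(diff(range(z9)), 4)  # five ring residues within a +/-2 A band
})
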
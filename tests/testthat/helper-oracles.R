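# Independent oracles and small fixture builders shared across tests.
# These deliberately re-derive quantities by brute force / direct formulas,
# not by calling the implementation paths they are used to check.

# Dense-grid inscribed-sphere oracle: exhaustive maximisation of
# min_atoms(|c - a| - vdw) over sphere centres on a fine grid in the plane.
oracle_pore_radius <- function(structure, z, lateral_max = 3, step = 0.05,
                               radii = hole_radii()) {
  s <- structure[structure$element != "H", , drop = FALSE]
  vdw <- unname(radii[s$element])
  vdw[is.na(vdw)] <- radii[["default"]]
  g <- seq(-lateral_max, lateral_max, by = step)
  cand <- expand.grid(cx = g, cy = g)
  cand <- cand[cand$cx^2 + cand$cy^2 <= lateral_max^2, ]
  best <- -Inf
  dz2 <- (s$z - z)^2
  f <- rep(Inf, nrow(cand))
  for (j in seq_len(nrow(s))) {
    d <- sqrt((cand$cx - s$x[j])^2 + (cand$cy - s$y[j])^2 + dz2[j]) - vdw[j]
    f <- pmin(f, d)
  }
  max(f)
}

# Brute-force rigid superposition: numeric minimisation of RMSD over an
# Euler-angle + translation parameterisation, multi-started.
oracle_superpose_rmsd <- function(P, Q, n_starts = 8) {
  rot_from_angles <- function(a) {
    cx <- cos(a[1]); sx <- sin(a[1])
    cy <- cos(a[2]); sy <- sin(a[2])
    cz <- cos(a[3]); sz <- sin(a[3])
    Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, 3, byrow = TRUE)
    Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3, byrow = TRUE)
    Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, 3, byrow = TRUE)
    Rz %*% Ry %*% Rx
  }
  obj <- function(p) {
    R <- rot_from_angles(p[1:3])
    moved <- sweep(P %*% t(R), 2, -p[4:6])
    sqrt(mean(rowSums((moved - Q)^2)))
  }
  best <- Inf
  set.seed(42)
  for (k in seq_len(n_starts)) {
    p0 <- c(runif(3, -pi, pi), colMeans(Q) - colMeans(P))
    o <- optim(p0, obj, method = "BFGS", control = list(maxit = 500,
                                                        reltol = 1e-14))
    o <- optim(o$par, obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-15))
    best <- min(best, o$value)
  }
  best
}

# Per-frame brute-force residue contact scan (any heavy atom within cutoff).
oracle_contact_freq <- function(traj, lig_idx, chain, resno, cutoff = 4.5) {
  top <- traj$topology
  ridx <- which(top$chain == chain & top$resno == resno & top$element != "H")
  lig_idx <- lig_idx[top$element[lig_idx] != "H"]
  nf <- n_frames(traj)
  hits <- 0L
  for (i in seq_len(nf)) {
    fr <- traj$coords[, , i]
    dmin <- Inf
    for (r in ridx) for (l in lig_idx)
      dmin <- min(dmin, sqrt(sum((fr[r, ] - fr[l, ])^2)))
    if (dmin <= cutoff) hits <- hits + 1L
  }
  hits / nf
}

# Brute-force water-at-gate count for one frame.
oracle_water_count <- function(traj, frame, gate_idx, cutoff = 3.0) {
  top <- traj$topology
  wat <- which(top$resid %in% c("HOH", "WAT", "TIP3", "SOL") &
                 top$element == "O")
  fr <- traj$coords[, , frame]
  n <- 0L
  for (w in wat) {
    d <- sqrt(colSums((t(fr[gate_idx, , drop = FALSE]) - fr[w, ])^2))
    if (any(d <= cutoff)) n <- n + 1L
  }
  n
}

# Exhaustive QT clustering for tiny frame sets: enumerate greedy extraction
# directly from the definition on a precomputed distance matrix.
oracle_qt_clusters <- function(D, cutoff, max_clusters) {
  n <- nrow(D)
  labels <- integer(n)
  cl <- 0L
  while (any(labels == 0L) && cl < max_clusters) {
    un <- which(labels == 0L)
    sizes <- vapply(un, function(i) sum(D[i, un] <= cutoff), integer(1))
    centre <- un[which.max(sizes)]
    members <- un[D[centre, un] <= cutoff]
    cl <- cl + 1L
    labels[members] <- cl
  }
  labels
}

# A plain ring-stack test structure (single chain, not prime-mapped).
ring_structure <- function(radius_fun, z_vals, n_ring = 24, vdw_element = "C",
                           ring_offset = 0.3) {
  rows <- list()
  for (i in seq_along(z_vals)) {
    z <- z_vals[i]
    a <- radius_fun(z) + hole_radii()[[vdw_element]]
    ang <- (i * ring_offset + 2 * pi * (seq_len(n_ring) - 1) / n_ring)
    rows[[i]] <- data.frame(chain = "A", resno = i, resid = "GLY",
                            elety = paste0("C", seq_len(n_ring)),
                            element = vdw_element,
                            x = a * cos(ang), y = a * sin(ang), z = z,
                            stringsAsFactors = FALSE)
  }
  as_structure(do.call(rbind, rows))
}

# Random smooth pore radius functions for property-style profiler tests.
random_radius_fun <- function(seed) {
  set.seed(seed)
  r0 <- runif(1, 2.0, 3.2)
  a1 <- runif(1, 0.2, 0.7)
  w <- runif(1, 0.2, 0.6)
  ph <- runif(1, 0, 2 * pi)
  function(z) r0 + a1 * sin(w * z + ph)
}
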
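#' Specification for a synthetic pentameric-channel dataset
#'
#' Collects every knob of the synthetic generator in one validated object so
#' that generation is a pure function of spec + seed and all parameters can
#' be serialised alongside the data. The generated systems are pseudo-C5
#' pentamers: five chains of pseudo-atom rings along +z realising a requested
#' pore radius profile, with M2-like residue numbering compatible with the
#' shipped prime map (prime k at axial position `(k + 2) * rise`, so the
#' -2' ring sits at z = 0), plus optional ligand, waters, upper-ECD groups
#' and per-residue contact probes.
#'
#' @param seed integer RNG seed, recorded in all outputs.
#' @param n_frames number of trajectory frames.
#' @param pore_radius function z (Angstrom) -> pore radius (Angstrom).
#' @param rise axial spacing between consecutive prime positions, Angstrom.
#' @param ring_step axial spacing of wall pseudo-atom rings, Angstrom.
#' @param atoms_per_ring wall pseudo-atoms per ring (shared by the 5 chains).
#' @param anchors named 9' anchor residue numbers per class.
#' @param chains named character vector chain id -> class (5 chains,
#'   alpha/alpha/beta/beta/gamma).
#' @param ligand_jitter_sigma per-frame isotropic rigid-body positional
#'   jitter of the ligand, Angstrom (sd per coordinate; frame 1 is exempt so
#'   traces start at 0).
#' @param ligand_drift systematic ligand drift along +z, Angstrom per frame
#'   (negative = toward the intracellular side).
#' @param ligand_z0 starting axial position of the ligand centre, Angstrom
#'   (default: the 5' ring position).
#' @param contact_schedule named numeric vector of contact fractions in
#'   [0, 1]; names are `"class:prime"` (e.g. `"alpha:2"`). Each scheduled
#'   residue (in every chain of the class) carries a probe atom placed within
#'   the contact cutoff of the ligand for exactly `round(f * n_frames)`
#'   leading frames. Duplicate names are a spec error.
#' @param water_plan list with `inside` (integer vector, recycled to
#'   `n_frames`: waters within the gate cutoff per frame) and `outside`
#'   (constant count of far-away waters).
#' @param breathing numeric vector (recycled to `n_frames`) of radial scale
#'   factors applied to the upper-ECD group centres about their centroid.
#' @param escape_frame frame at which the ligand leaves its pocket in
#'   [make_unbinding_trajectory()].
#' @param frame_interval trajectory sampling interval, ns.
#' @return object of class `SyntheticSpec`.
#' @export
synthetic_spec <- function(seed = 1L, n_frames = 100L,
                           pore_radius = function(z) rep(4.5, length(z)),
                           rise = 1.5, ring_step = 0.5, atoms_per_ring = 24L,
                           anchors = c(alpha = 264L, beta = 259L, gamma = 274L),
                           chains = c(A = "alpha", B = "beta", C = "alpha",
                                      D = "beta", E = "gamma"),
                           ligand_jitter_sigma = 0, ligand_drift = 0,
                           ligand_z0 = NULL, contact_schedule = NULL,
                           water_plan = NULL, breathing = NULL,
                           escape_frame = NULL, frame_interval = 0.4) {
  stopifnot(n_frames >= 1, rise > 0, ring_step > 0, atoms_per_ring >= 10,
            frame_interval > 0, length(chains) == 5)
  if (!is.null(contact_schedule)) {
    if (anyDuplicated(names(contact_schedule)))
      stop("spec error: contradictory contact schedule (duplicate residue)")
    if (any(contact_schedule < 0 | contact_schedule > 1))
      stop("spec error: contact fractions must lie in [0, 1]")
  }
  if (!is.null(water_plan))
    stopifnot(is.list(water_plan), all(water_plan$inside >= 0),
              length(water_plan$outside %||% 0L) == 1)
  spec <- list(seed = as.integer(seed), n_frames = as.integer(n_frames),
               pore_radius = pore_radius, rise = rise, ring_step = ring_step,
               atoms_per_ring = as.integer(atoms_per_ring), anchors = anchors,
               chains = chains, ligand_jitter_sigma = ligand_jitter_sigma,
               ligand_drift = ligand_drift, ligand_z0 = ligand_z0,
               contact_schedule = contact_schedule, water_plan = water_plan,
               breathing = breathing, escape_frame = escape_frame,
               frame_interval = frame_interval)
  class(spec) <- "SyntheticSpec"
  spec
}

.prime_span <- function(spec) {
  list(primes = -2:20, z = ( -2:20 + 2) * spec$rise,
       z_lim = c(0, 22 * spec$rise))
}

.residue_name <- function(class, prime) {
  if (prime == 9) return("LEU")
  if (prime == 2) return(switch(class, alpha = "VAL", beta = "ALA", "SER"))
  "GLY"
}

#' Build a ground-truthed synthetic pentameric channel
#'
#' Five pseudo-subunits of carbon pseudo-atom rings along +z realising the
#' requested pore radius profile analytically: every wall ring at axial
#' position z has radius `pore_radius(z) + 1.85` (the carbon vdW radius of
#' the shipped table), so the maximal inscribed sphere at z has radius
#' `pore_radius(z)` up to ring discretisation (< 0.01 Angstrom for the
#' default spacing). Atoms are apportioned to the five chains by angular
#' sector and numbered so the shipped prime map applies.
#'
#' @param spec a `SyntheticSpec`.
#' @return list with `structure` (a `Structure`), `truth` (data frame z,
#'   radius of the programmed profile on a 0.25 Angstrom grid) and `spec`.
#' @export
make_toy_channel <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  span <- .prime_span(spec)
  zg <- seq(span$z_lim[1], span$z_lim[2], by = 0.25)
  Rz <- spec$pore_radius(zg)
  if (any(!is.finite(Rz)) || any(Rz <= 0.5))
    stop("parameter error: pore radius must exceed 0.5 Angstrom everywhere")
  ring_z <- seq(span$z_lim[1], span$z_lim[2], by = spec$ring_step)
  n <- spec$atoms_per_ring
  golden <- 2.399963229728653
  chains <- names(spec$chains)
  rows <- vector("list", length(ring_z))
  for (i in seq_along(ring_z)) {
    z <- ring_z[i]
    a <- spec$pore_radius(z) + 1.85
    ang <- ((i - 1) * golden + 2 * pi * (seq_len(n) - 1) / n) %% (2 * pi)
    sector <- pmin(floor(ang / (2 * pi / 5)) + 1, 5)
    k <- min(max(round(z / spec$rise) - 2, -2L), 20L)
    cls <- spec$chains[sector]
    rows[[i]] <- data.frame(
      chain = chains[sector],
      resno = as.integer(spec$anchors[cls] + k - 9L),
      resid = vapply(cls, .residue_name, "", prime = k),
      x = a * cos(ang), y = a * sin(ang), z = z,
      stringsAsFactors = FALSE)
  }
  at <- do.call(rbind, rows)
  at <- at[order(match(at$chain, chains), at$resno), ]
  # unique atom names per residue; first atom of each residue is its CA
  grp <- paste(at$chain, at$resno)
  idx_in_res <- stats::ave(seq_len(nrow(at)), grp, FUN = seq_along)
  at$elety <- ifelse(idx_in_res == 1, "CA", paste0("C", idx_in_res))
  at$element <- "C"
  s <- as_structure(at)
  list(structure = s,
       truth = data.frame(z = zg, radius = Rz),
       spec = spec)
}

# Deterministic 12-heavy-atom pseudo-steroid: elongated helical blob along z,
# COM at the origin, sulfate-like sulfur at the +z end.
.ligand_template <- function() {
  j <- 0:11
  xyz <- cbind(0.7 * cos(j * 0.7), 0.7 * sin(j * 0.7), -2 + j * 0.36)
  xyz <- sweep(xyz, 2, colMeans(xyz))
  data.frame(chain = "X", resno = 1L, resid = "DHS",
             elety = c(paste0("C", 1:10), "O1", "S1"),
             element = c(rep("C", 10), "O", "S"),
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             stringsAsFactors = FALSE)
}

# One upper-ECD pseudo-group (8 residues x 3 atoms) in local coordinates;
# rotated per chain about z for exact C5 symmetry. Mixed elements so mass
# weighting is exercised.
.ecd_template <- function() {
  r <- rep(1:8, each = 3)
  a <- (seq_len(24) - 1) * 0.9
  data.frame(resno = r,
             resid = "GLY",
             elety = rep(c("N", "CA", "C"), 8),
             element = rep(c("N", "C", "C"), 8),
             x = 1.5 * cos(a), y = 1.5 * sin(a), z = (r - 4.5) * 0.8,
             stringsAsFactors = FALSE)
}

.rot_z <- function(theta)
  matrix(c(cos(theta), -sin(theta), 0, sin(theta), cos(theta), 0, 0, 0, 1),
         3, 3, byrow = TRUE)

#' Build a ground-truthed synthetic trajectory
#'
#' Assembles a static channel (from [make_toy_channel()]) plus, as requested
#' by the spec: a pore ligand with programmed rigid-body jitter and axial
#' drift; per-residue contact probes realising an exact contact schedule;
#' waters realising per-frame gate hydration counts; and five upper-ECD
#' pseudo-groups whose centres breathe radially by programmed scale factors.
#' Ground truth for every downstream observable is emitted in the same
#' schemas the analysis functions output.
#'
#' @param spec a `SyntheticSpec`.
#' @param contact_cutoff cutoff the schedule is realised against, Angstrom.
#' @param hydration_cutoff gate-water cutoff realised by the water plan.
#' @return list with `trajectory` (a `Trajectory`), `truth` (list: `rmsd`,
#'   `z`, `contacts`, `hydration`, `spread`, `com_displacement`) and `spec`.
#' @export
make_toy_trajectory <- function(spec, contact_cutoff = 4.5,
                                hydration_cutoff = 3.0) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  chan <- make_toy_channel(spec)$structure
  span <- .prime_span(spec)
  nf <- spec$n_frames
  chains <- names(spec$chains)
  parts <- list(chan)

  # upper-ECD groups, one per chain, exactly C5-symmetric
  ecd_loc <- .ecd_template()
  z_top <- span$z_lim[2] + 6
  ecd_list <- list()
  for (i in seq_len(5)) {
    th <- (i - 1) * 2 * pi / 5
    xyz <- as.matrix(ecd_loc[, c("x", "y", "z")]) %*% t(.rot_z(th))
    ctr <- c(12 * cos(th), 12 * sin(th), z_top)
    df <- ecd_loc
    df$x <- xyz[, 1] + ctr[1]; df$y <- xyz[, 2] + ctr[2]
    df$z <- xyz[, 3] + ctr[3]
    df$chain <- chains[i]
    ecd_list[[i]] <- df[, c("chain", "resno", "resid", "elety", "element",
                            "x", "y", "z")]
  }
  ecd <- do.call(rbind, ecd_list)
  parts <- c(parts, list(ecd))

  # contact probes: one extra atom per scheduled residue
  probe_rows <- NULL
  probe_meta <- NULL
  if (!is.null(spec$contact_schedule)) {
    for (nm in names(spec$contact_schedule)) {
      pp <- strsplit(nm, ":", fixed = TRUE)[[1]]
      cls <- pp[1]; k <- as.integer(pp[2])
      if (!cls %in% spec$chains || k < -2 || k > 20)
        stop("spec error: unknown contact-schedule key ", nm)
      for (ch in chains[spec$chains == cls]) {
        rn <- as.integer(spec$anchors[[cls]] + k - 9L)
        zk <- (k + 2) * spec$rise
        a_out <- spec$pore_radius(zk) + 1.85 + 8
        th <- (match(ch, chains) - 0.5) * 2 * pi / 5
        probe_rows <- rbind(probe_rows, data.frame(
          chain = ch, resno = rn, resid = .residue_name(cls, k),
          elety = "CX", element = "C",
          x = a_out * cos(th), y = a_out * sin(th), z = zk,
          stringsAsFactors = FALSE))
        probe_meta <- rbind(probe_meta, data.frame(
          chain = ch, resno = rn, frac = spec$contact_schedule[[nm]],
          theta = th, zk = zk, stringsAsFactors = FALSE))
      }
    }
    parts <- c(parts, list(probe_rows))
  }

  # ligand
  lig <- .ligand_template()
  z0 <- spec$ligand_z0 %||% ((5 + 2) * spec$rise)
  lig$z <- lig$z + z0
  parts <- c(parts, list(lig))

  # waters: enough molecules for the plan; base positions far from the gate
  wp <- spec$water_plan
  inside_plan <- if (is.null(wp)) rep(0L, nf)
                 else rep_len(as.integer(wp$inside), nf)
  n_out <- if (is.null(wp)) 0L else as.integer(wp$outside %||% 0L)
  n_wat <- max(inside_plan) + n_out
  z9 <- (9 + 2) * spec$rise
  gate_a <- spec$pore_radius(z9) + 1.85
  golden_angle <- 2.399963229728653
  far_pos <- function(j) {
    th <- j * golden_angle
    c(15 * cos(th), 15 * sin(th), z9 + 20 + 2 * j)
  }
  wat <- NULL
  if (n_wat > 0)
    wat <- data.frame(chain = "W", resno = seq_len(n_wat), resid = "HOH",
                      elety = "O", element = "O",
                      x = vapply(seq_len(n_wat), function(j) far_pos(j)[1], 0),
                      y = vapply(seq_len(n_wat), function(j) far_pos(j)[2], 0),
                      z = vapply(seq_len(n_wat), function(j) far_pos(j)[3], 0),
                      stringsAsFactors = FALSE)
  if (!is.null(wat)) parts <- c(parts, list(wat))

  base <- as_structure(do.call(rbind, lapply(parts, function(p)
    p[, c("chain", "resno", "resid", "elety", "element", "x", "y", "z")])))
  nat <- nrow(base)
  lig_idx <- which(base$resid == "DHS")
  wat_idx <- which(base$resid == "HOH")
  base_xyz <- coords(base)

  # per-frame displacements (seeded; frame 1 exempt from jitter/drift)
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(spec$seed)
  jit <- matrix(0, nf, 3)
  if (spec$ligand_jitter_sigma > 0 && nf > 1)
    jit[-1, ] <- matrix(rnorm(3 * (nf - 1), sd = spec$ligand_jitter_sigma),
                        nf - 1, 3)
  disp <- cbind(jit[, 1], jit[, 2],
                jit[, 3] + spec$ligand_drift * (seq_len(nf) - 1))

  breathing <- if (is.null(spec$breathing)) rep(1, nf)
               else rep_len(spec$breathing, nf)
  ecd_idx_by_chain <- lapply(chains, function(ch)
    which(base$chain == ch & base$resno <= 8 & base$elety %in% c("N", "CA", "C")))
  names(ecd_idx_by_chain) <- chains
  masses <- atom_masses(base)
  ecd_com <- t(vapply(ecd_idx_by_chain, function(idx) {
    m <- masses[idx]
    colSums(base_xyz[idx, , drop = FALSE] * m) / sum(m)
  }, numeric(3)))
  ecd_ctr <- colMeans(ecd_com)
  d0 <- mean(sqrt(rowSums(sweep(ecd_com, 2, ecd_ctr)^2)))

  frames <- array(NA_real_, dim = c(nat, 3, nf))
  lig_com <- centre_of_mass(base, sel = lig_idx)
  for (t in seq_len(nf)) {
    fr <- base_xyz
    # ligand rigid displacement
    fr[lig_idx, ] <- sweep(base_xyz[lig_idx, , drop = FALSE], 2, -disp[t, ])
    com_t <- lig_com + disp[t, ]
    # contact probes: inside cutoff for the leading scheduled frames
    if (!is.null(probe_meta)) {
      for (p in seq_len(nrow(probe_meta))) {
        row <- which(base$chain == probe_meta$chain[p] &
                       base$resno == probe_meta$resno[p] &
                       base$elety == "CX")
        k_in <- round(probe_meta$frac[p] * nf)
        if (t <= k_in)
          fr[row, ] <- com_t + 2.0 * c(cos(probe_meta$theta[p]),
                                       sin(probe_meta$theta[p]), 0)
      }
    }
    # waters: first inside_plan[t] molecules placed 2.5 A inside the gate wall
    if (length(wat_idx) && inside_plan[t] > 0) {
      for (j in seq_len(inside_plan[t])) {
        th <- j * 2 * pi / max(inside_plan[t], 1)
        g <- c(gate_a * cos(th), gate_a * sin(th), z9)
        dir <- c(-cos(th), -sin(th), 0)
        fr[wat_idx[j], ] <- g + 2.5 * dir
      }
    }
    # upper-ECD breathing: shift each group rigidly, radially about centroid
    if (breathing[t] != 1) {
      for (ch in chains) {
        idx <- ecd_idx_by_chain[[ch]]
        shift <- (breathing[t] - 1) * (ecd_com[ch, ] - ecd_ctr)
        fr[idx, ] <- sweep(fr[idx, , drop = FALSE], 2, -shift)
      }
    }
    frames[, , t] <- fr
  }

  truth <- list(
    rmsd = data.frame(frame = seq_len(nf),
                      rmsd = sqrt(rowSums(disp^2))),
    z = data.frame(frame = seq_len(nf), dz = disp[, 3]),
    contacts = if (is.null(probe_meta)) NULL else
      data.frame(chain = probe_meta$chain, resno = probe_meta$resno,
                 frequency = round(probe_meta$frac * nf) / nf),
    hydration = data.frame(frame = seq_len(nf), count = inside_plan),
    spread = data.frame(frame = seq_len(nf),
                        value = breathing * d0),
    com_displacement = data.frame(frame = seq_len(nf),
                                  value = abs(breathing - breathing[1]) * d0))

  list(trajectory = as_trajectory(base, frames,
                                  frame_interval = spec$frame_interval),
       truth = truth, spec = spec)
}

#' Build a synthetic agonist-unbinding trajectory
#'
#' The ligand stays in its pocket (small seeded jitter) until the programmed
#' escape frame, after which it departs along +x far beyond the 60 Angstrom
#' crop threshold, so a downstream RMSD trace with the published crop preset
#' flags exactly the post-escape frames.
#'
#' @param spec a `SyntheticSpec` with a non-NULL `escape_frame`.
#' @return list with `trajectory`, `escape_frame` and `spec`. When
#'   `escape_frame` is NULL the ligand never leaves (no-escape control).
#' @export
make_unbinding_trajectory <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  chan <- make_toy_channel(spec)$structure
  lig <- .ligand_template()
  span <- .prime_span(spec)
  lig$x <- lig$x + 9; lig$z <- lig$z + span$z_lim[2] + 8  # pocket above TMD
  base <- as_structure(rbind(
    chan[, c("chain", "resno", "resid", "elety", "element", "x", "y", "z")],
    lig[, c("chain", "resno", "resid", "elety", "element", "x", "y", "z")]))
  nf <- spec$n_frames
  lig_idx <- which(base$resid == "DHS")
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(spec$seed)
  base_xyz <- coords(base)
  frames <- array(NA_real_, dim = c(nrow(base), 3, nf))
  sig <- max(spec$ligand_jitter_sigma, 0)
  esc <- spec$escape_frame
  for (t in seq_len(nf)) {
    fr <- base_xyz
    d <- if (t > 1 && sig > 0) rnorm(3, sd = sig) else c(0, 0, 0)
    if (!is.null(esc) && t >= esc)
      d <- d + c(70 + 3 * (t - esc), 0, 0)
    fr[lig_idx, ] <- sweep(base_xyz[lig_idx, , drop = FALSE], 2, -d)
    frames[, , t] <- fr
  }
  list(trajectory = as_trajectory(base, frames,
                                  frame_interval = spec$frame_interval),
       escape_frame = esc, spec = spec)
}

# Analytic inscribed-sphere radius of a ring-built wall: the sphere centred
# on the axis at z is limited by every wall ring, so
# I(z) = min over ring positions z' of sqrt((R(z') + rc)^2 + (z - z')^2) - rc.
.inscribed_on_axis <- function(rad_fun, z, ring_z, rc = 1.85) {
  a <- rad_fun(ring_z) + rc
  vapply(z, function(zz) min(sqrt(a^2 + (zz - ring_z)^2)) - rc, numeric(1))
}

#' Synthetic stand-in channels emulating modulated pore states
#'
#' Convenience wrapper around [make_toy_channel()] with smooth pore radius
#' profiles whose prime-position gate diameters emulate the published
#' geometry of four receptor states: agonist alone (9' constriction 4.6
#' Angstrom, global constriction at -2'), agonist + allopregnanolone (9'
#' dilated to 9.1, pore widest between 17' and 20'), etomidate (9' 8.4) and
#' propofol (10.5). These are synthetic constructions for exercising the
#' measurement pipeline, not deposited coordinates.
#'
#' Because the maximal inscribed sphere at a flaring section is clipped by
#' the neighbouring constriction walls, a wall built naively from the target
#' radii would measure systematically narrow. The generator therefore
#' calibrates its spline control radii by fixed-point iteration until its
#' own analytic inscribed-sphere profile, evaluated with the same slab-
#' minimum rule as [gate_diameters()], reproduces the programmed diameters.
#'
#' @param state one of `"gaba"`, `"gaba_allo"`, `"etomidate"`, `"propofol"`.
#' @param seed seed stored in the spec (the construction is deterministic).
#' @param slab_half_width slab rule matched during calibration, Angstrom.
#' @return as [make_toy_channel()], plus `control_diameters` (the programmed
#'   prime -> diameter table) and `state`; the `truth` profile is the
#'   analytic inscribed-sphere radius of the calibrated wall.
#' @export
synthetic_state_channel <- function(state = c("gaba", "gaba_allo",
                                              "etomidate", "propofol"),
                                    seed = 1L, slab_half_width = 1.5) {
  state <- match.arg(state)
  # enforced gate diameters at the cited primes; primes 0, 7 and 11 are tied
  # shape controls (shelf above the -2' climb; shoulders making 9' a local
  # constriction, as the leucine ring is), not calibration targets
  primes <- c(-2, 0, 2, 5, 7, 9, 11, 13, 17, 18, 20)
  enforce <- !(primes %in% c(0, 7, 11))
  diam <- switch(state,
    gaba      = c(2.4, NA, 5.6, 5.4, NA, 4.6, NA, 7.0, 9.4, 9.6, 9.0),
    gaba_allo = c(2.4, NA, 5.6, 6.4, NA, 9.1, NA, 10.8, 12.8, 13.4, 12.6),
    etomidate = c(2.6, NA, 5.6, 6.2, NA, 8.4, NA, 10.0, 11.6, 12.0, 11.2),
    propofol  = c(2.6, NA, 6.2, 8.0, NA, 10.5, NA, 11.8, 12.8, 13.2, 12.4))
  spec <- synthetic_spec(seed = seed)
  zs <- (primes + 2) * spec$rise
  z_lim <- c(0, 22 * spec$rise)
  ring_z <- seq(z_lim[1], z_lim[2], by = spec$ring_step)
  zg <- seq(z_lim[1], z_lim[2], by = 0.25)
  target <- diam / 2
  tie <- function(ctrl) {
    ctrl[primes == 0] <- ctrl[primes == 2]
    ctrl[primes %in% c(7, 11)] <- ctrl[primes == 9] + 1.2
    ctrl
  }
  ctrl <- tie(ifelse(enforce, target, 0))
  make_fun <- function(ctrl) {
    f <- stats::splinefun(zs, ctrl, method = "monoH.FC")
    function(z) f(pmin(pmax(z, z_lim[1]), z_lim[2]))
  }
  slab_min <- function(rad_fun) {
    prof <- .inscribed_on_axis(rad_fun, zg, ring_z)
    vapply(zs, function(zc) {
      inw <- zg >= zc - slab_half_width & zg <= zc + slab_half_width
      min(prof[inw])
    }, numeric(1))
  }
  for (it in 1:100) {
    measured <- slab_min(make_fun(ctrl))
    err <- ifelse(enforce, target - measured, 0)
    if (max(abs(err)) < 1e-4) break
    ctrl <- tie(pmin(pmax(ctrl + 0.8 * err, 0.8), 9))
  }
  key <- primes %in% c(-2, 9)
  if (max(abs(err[key])) > 0.05)
    warning("state-channel calibration residual ",
            round(max(abs(err[key])), 3),
            " Angstrom at a gate prime (diameters jointly near-infeasible)")
  spec$pore_radius <- make_fun(ctrl)
  out <- make_toy_channel(spec)
  out$truth <- data.frame(z = zg,
                          radius = .inscribed_on_axis(spec$pore_radius, zg,
                                                      ring_z))
  out$control_diameters <- data.frame(prime = primes[enforce],
                                      diameter = diam[enforce])
  out$state <- state
  out
}
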
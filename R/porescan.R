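#' HOLE-style simple van der Waals radius table
#'
#' The classic simple radius set used for inscribed-sphere pore profiling:
#' C 1.85, O 1.65, N 1.75, S 2.00, H 1.00, P 2.10 Angstrom. Elements absent
#' from the table fall back to `default`.
#'
#' @return named numeric vector of radii (Angstrom) with a `default` entry.
#' @export
hole_radii <- function() {
  c(C = 1.85, O = 1.65, N = 1.75, S = 2.00, H = 1.00, P = 2.10, default = 2.00)
}

.vdw_lookup <- function(element, radii) {
  r <- radii[element]
  fallback <- if ("default" %in% names(radii)) radii[["default"]] else 2.00
  r[is.na(r)] <- fallback
  unname(r)
}

# Clearance of a sphere centre (cx, cy, z) against atoms: min over atoms of
# (distance - vdw). Vectorised over centres.
.clearance <- function(cx, cy, z, ax, ay, az, vdw) {
  if (length(cx) == 1L)
    return(min(sqrt((cx - ax)^2 + (cy - ay)^2 + (z - az)^2) - vdw))
  m <- length(cx)
  best <- rep(Inf, m)
  dz2 <- (az - z)^2
  for (j in seq_along(ax)) {
    d <- sqrt((cx - ax[j])^2 + (cy - ay[j])^2 + dz2[j]) - vdw[j]
    sel <- d < best
    best[sel] <- d[sel]
  }
  best
}

#' Inscribed-sphere pore radius profile along the channel axis
#'
#' For an axis-aligned structure (pore axis = z through the origin; see
#' [align_pore_axis()]) computes, at each axial position z, the radius of the
#' largest sphere centred in the plane at z (within a lateral search disc
#' about the axis) that touches no atom:
#' `radius(z) = max over centres of min over atoms (|centre - atom| - vdw)`.
#' The maximisation is a deterministic coarse 2-d grid search followed by
#' Nelder-Mead refinement from the best grid point, so repeated runs are
#' bit-identical. Slices with no atoms within reach are flagged as gaps
#' (`NA` radius), never silently reported as zero.
#'
#' @param structure an axis-aligned `Structure`.
#' @param z_range length-2 axial interval, Angstrom (default: atom z extent).
#' @param grid axial step, Angstrom (default 0.25).
#' @param radii named vdW radius table (default [hole_radii()]); the set name
#'   is recorded in the result.
#' @param radii_set_name label recorded alongside the profile.
#' @param lateral_max radius of the lateral search disc about the axis,
#'   Angstrom (default 8).
#' @param coarse_step coarse grid spacing for the 2-d search (default 0.5).
#' @param include_hydrogens include H atoms (default FALSE; deposited models
#'   are heavy-atom).
#' @param track follow the pore lumen: slices are processed outward from the
#'   seed slice and each slice's search is confined to within `track_radius`
#'   of the previous slice's sphere centre (plus the axis disc). This keeps
#'   the search inside the pore near the open channel mouths, where the
#'   unconstrained disc maximum lies outside the wall. Disable for a pure
#'   per-slice disc maximisation.
#' @param track_radius maximal lateral movement of the sphere centre between
#'   adjacent slices when tracking, Angstrom.
#' @param seed_z axial position of the tracking seed slice (default: middle
#'   of `z_range`; the search there is the unconstrained disc maximum).
#' @return object of class `PoreProfile`: data frame (z, radius, cx, cy) with
#'   attributes `radii_set_name`, `lateral_max`, `grid`, `axis`.
#' @export
pore_profile <- function(structure, z_range = NULL, grid = 0.25,
                         radii = hole_radii(), radii_set_name = "hole_simple",
                         lateral_max = 8, coarse_step = 0.5,
                         include_hydrogens = FALSE, track = TRUE,
                         track_radius = 2.5, seed_z = NULL) {
  stopifnot(inherits(structure, "Structure"), grid > 0, lateral_max > 0)
  s <- structure
  if (!include_hydrogens) s <- s[s$element != "H", , drop = FALSE]
  if (nrow(s) == 0) stop("no atoms left after hydrogen filtering")
  ax <- s$x; ay <- s$y; az <- s$z
  vdw <- .vdw_lookup(s$element, radii)
  if (is.null(z_range)) z_range <- range(az)
  if (z_range[1] < min(az) - 1e-9 || z_range[2] > max(az) + 1e-9)
    stop("z_range extends beyond the atom extent [", round(min(az), 2), ", ",
         round(max(az), 2), "]")
  zs <- seq(z_range[1], z_range[2], by = grid)
  # coarse candidate centres on a square grid inside the search disc
  g <- seq(-lateral_max, lateral_max, by = coarse_step)
  cand <- expand.grid(cx = g, cy = g)
  cand <- cand[cand$cx^2 + cand$cy^2 <= lateral_max^2, ]
  dz_max <- lateral_max + max(vdw) + 6
  res <- data.frame(z = zs, radius = NA_real_, cx = NA_real_, cy = NA_real_)
  if (is.null(seed_z)) seed_z <- mean(z_range)
  i0 <- which.min(abs(zs - seed_z))
  solve_slice <- function(z, prev) {
    near <- which(abs(az - z) <= dz_max)
    if (length(near) == 0) return(NULL)  # gap flagged as NA
    use <- rep(TRUE, nrow(cand))
    if (track && !is.null(prev)) {
      use <- (cand$cx - prev[1])^2 + (cand$cy - prev[2])^2 <= track_radius^2
      if (!any(use)) use <- rep(TRUE, nrow(cand))
    }
    f <- .clearance(cand$cx[use], cand$cy[use], z, ax[near], ay[near],
                    az[near], vdw[near])
    start <- c(cand$cx[use][which.max(f)], cand$cy[use][which.max(f)])
    opt <- stats::optim(start, function(p) {
      if (p[1]^2 + p[2]^2 > lateral_max^2) return(1e6)
      if (track && !is.null(prev) &&
          (p[1] - prev[1])^2 + (p[2] - prev[2])^2 > track_radius^2)
        return(1e6)
      -.clearance(p[1], p[2], z, ax[near], ay[near], az[near], vdw[near])
    }, method = "Nelder-Mead",
    control = list(reltol = 1e-10, maxit = 400))
    if (-opt$value >= max(f)) list(r = -opt$value, ctr = opt$par)
    else list(r = max(f), ctr = start)
  }
  for (branch in list(seq(i0, length(zs)), if (i0 > 1) seq(i0 - 1, 1))) {
    prev <- if (!is.null(branch) && branch[1] != i0 && is.finite(res$cx[i0]))
      c(res$cx[i0], res$cy[i0]) else NULL
    for (i in branch) {
      sol <- solve_slice(zs[i], prev)
      if (is.null(sol)) { prev <- NULL; next }
      res$radius[i] <- max(0, sol$r)
      res$cx[i] <- sol$ctr[1]; res$cy[i] <- sol$ctr[2]
      prev <- sol$ctr
    }
  }
  structure(res, radii_set_name = radii_set_name, lateral_max = lateral_max,
            grid = grid, coarse_step = coarse_step,
            axis = list(origin = c(0, 0, 0), direction = c(0, 0, 1)),
            class = c("PoreProfile", "data.frame"))
}

#' Minimal pore diameters at M2 prime positions
#'
#' For each mapped prime position, locates the ring slab (mean z of the ring
#' residues' atoms, plus/minus `slab_half_width`) and reports twice the
#' minimal profile radius inside the slab together with the z of the minimum.
#' Prime positions whose ring residues are absent from the structure, or
#' whose slab contains no sampled profile point, are omitted with a warning.
#'
#' @param profile a `PoreProfile` (same axis frame as `structure`).
#' @param prime_map a `PrimeMap`.
#' @param structure the axis-aligned `Structure` the profile was computed on.
#' @param slab_half_width half-width of the axial slab around each ring's
#'   mean z, Angstrom (default 1.5).
#' @return object of class `GateReport`: data frame (prime, diameter, z_min,
#'   z_ring, n_chains) sorted by prime index; attribute `slab_half_width`.
#' @export
gate_diameters <- function(profile, prime_map, structure,
                           slab_half_width = 1.5) {
  stopifnot(inherits(profile, "PoreProfile"), inherits(prime_map, "PrimeMap"),
            inherits(structure, "Structure"))
  primes <- sort(unique(prime_map$prime))
  out <- list()
  for (k in primes) {
    res <- prime_residues(prime_map, k)
    idx <- integer(0)
    for (i in seq_len(nrow(res)))
      idx <- c(idx, select_atoms(structure, chain = res$chain[i],
                                 resno = res$resno[i]))
    if (length(idx) == 0) {
      warning("prime ", k, ": ring residues missing; position omitted")
      next
    }
    zc <- mean(structure$z[idx])
    in_slab <- which(profile$z >= zc - slab_half_width &
                       profile$z <= zc + slab_half_width &
                       is.finite(profile$radius))
    if (length(in_slab) == 0) {
      warning("prime ", k, ": no sampled profile point in slab; omitted")
      next
    }
    j <- in_slab[which.min(profile$radius[in_slab])]
    nch <- length(unique(structure$chain[idx]))
    out[[as.character(k)]] <- data.frame(
      prime = k, diameter = 2 * profile$radius[j], z_min = profile$z[j],
      z_ring = zc, n_chains = nch)
  }
  rep <- do.call(rbind, out)
  rownames(rep) <- NULL
  structure(rep, slab_half_width = slab_half_width,
            class = c("GateReport", "data.frame"))
}
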
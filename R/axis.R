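#' Align the pseudo-C5 pore axis of a pentamer to +z
#'
#' The pore axis is defined as the principal eigenvector (largest eigenvalue)
#' of the inertia tensor of the five per-subunit M2 C-alpha centroids taken
#' about their mean: for five points arranged on a ring, that eigenvector is
#' the ring normal. The structure is rotated so this axis maps onto +z and
#' translated so the ring centroid sits at the origin. The sign of the axis
#' is chosen so the extracellular side points to +z, using (in order of
#' preference) the supplied ECD selection's centroid, else the mean position
#' of the highest mapped prime ring versus the lowest (the high-prime end of
#' M2 is extracellular).
#'
#' @param structure a `Structure`.
#' @param subunits a `SubunitMap` (5 chains).
#' @param prime_map a `PrimeMap` for the structure; defines the M2 residue
#'   span per chain and the extracellular direction.
#' @param ecd_selection optional `Selection` of extracellular-domain atoms
#'   used only to orient the axis sign.
#' @return list with `structure` (aligned), `transform` (`RigidTransform`
#'   applied), `origin` (always `c(0,0,0)` in the aligned frame) and
#'   `direction` (`c(0,0,1)`).
#' @export
align_pore_axis <- function(structure, subunits, prime_map,
                            ecd_selection = NULL) {
  stopifnot(inherits(structure, "Structure"), inherits(subunits, "SubunitMap"),
            inherits(prime_map, "PrimeMap"))
  if (nrow(subunits) != 5)
    stop("subunit-count error: pore-axis alignment needs a pentamer")
  xyz <- coords(structure)
  cents <- matrix(NA_real_, 5, 3)
  for (i in seq_len(5)) {
    ch <- subunits$chain[i]
    resnos <- prime_map$resno[prime_map$chain == ch]
    idx <- select_atoms(structure, chain = ch, resno = resnos, elety = "CA")
    if (length(idx) == 0)  # pseudo-atom fixtures may lack CA records
      idx <- select_atoms(structure, chain = ch, resno = resnos)
    if (length(idx) == 0)
      stop("no M2 atoms found in chain ", ch)
    cents[i, ] <- colMeans(xyz[idx, , drop = FALSE])
  }
  ctr <- colMeans(cents)
  rel <- sweep(cents, 2, ctr)
  # inertia tensor of the centroid ring (unit masses)
  inert <- diag(sum(rel^2), 3) - crossprod(rel)
  eig <- eigen(inert, symmetric = TRUE)
  axis <- eig$vectors[, 1]
  # orient: extracellular side -> +z
  ref_vec <- NULL
  if (!is.null(ecd_selection) && length(ecd_selection)) {
    ref_vec <- colMeans(xyz[ecd_selection, , drop = FALSE]) - ctr
  } else {
    pr <- attr(prime_map, "prime_range")
    hi <- select_prime_ring(structure, prime_map, pr[2])
    lo <- select_prime_ring(structure, prime_map, pr[1])
    if (length(hi) && length(lo))
      ref_vec <- colMeans(xyz[hi, , drop = FALSE]) -
        colMeans(xyz[lo, , drop = FALSE])
  }
  if (!is.null(ref_vec) && sum(axis * ref_vec) < 0) axis <- -axis
  R <- .rotation_to_z(axis)
  tr <- rigid_transform(R, as.numeric(-R %*% ctr))
  list(structure = apply_transform(structure, tr), transform = tr,
       origin = c(0, 0, 0), direction = c(0, 0, 1))
}

# Rotation matrix taking unit vector v onto +z (Rodrigues construction).
.rotation_to_z <- function(v) {
  v <- v / sqrt(sum(v^2))
  z <- c(0, 0, 1)
  c_ <- sum(v * z)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) return(diag(c(1, -1, -1)))  # pi about x
  k <- c(v[2] * z[3] - v[3] * z[2], v[3] * z[1] - v[1] * z[3],
         v[1] * z[2] - v[2] * z[1])
  s <- sqrt(sum(k^2)); k <- k / s
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + s * K + (1 - c_) * (K %*% K)
}

#' Apply an existing axis alignment to a trajectory
#' @param traj a `Trajectory`.
#' @param tr a `RigidTransform` from [align_pore_axis()].
#' @return the transformed `Trajectory`.
#' @export
transform_trajectory <- function(traj, tr) {
  for (i in seq_len(n_frames(traj)))
    traj$coords[, , i] <- apply_transform(traj$coords[, , i], tr)
  traj$topology <- apply_transform(traj$topology, tr)
  traj
}
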
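.resolve_reference <- function(traj, reference) {
  if (inherits(reference, "Structure")) {
    if (nrow(reference) != nrow(traj$topology))
      stop("reference structure does not match the trajectory topology")
    coords(reference)
  } else {
    frame_coords(traj, as.integer(reference))
  }
}

.align_frame <- function(fr, ref, align) {
  if (is.null(align) || length(align) < 3) return(fr)
  k <- .kabsch(fr[align, , drop = FALSE], ref[align, , drop = FALSE])
  sweep(fr %*% t(k$rotation), 2, -k$translation)
}

#' Ligand RMSD trace over a trajectory
#'
#' Each frame is first rigid-body superposed onto the reference using the
#' alignment selection (protein C-alpha atoms by default); the RMSD is then
#' computed over the ligand heavy atoms without further fitting, so genuine
#' ligand motion relative to the protein is measured. An optional crop rule
#' replaces raw values above `crop_threshold` by `crop_value` and flags them,
#' which keeps unbinding excursions (raw RMSD far beyond the plot range) on a
#' comparable scale.
#'
#' @param traj a `Trajectory`.
#' @param ligand `Selection` of ligand atoms (heavy atoms recommended).
#' @param align `Selection` used for the per-frame superposition; default the
#'   protein C-alpha atoms of the topology.
#' @param reference reference for both alignment and RMSD: a 1-based frame
#'   index (default 1, the starting pose) or an external `Structure` sharing
#'   the topology.
#' @param crop_threshold crop rule threshold, Angstrom (`NULL` = no crop).
#' @param crop_value stored value for cropped frames, Angstrom.
#' @return object of class `RmsdTrace`: data frame (frame, time_ns, rmsd,
#'   raw_rmsd, cropped); attributes `crop_threshold`, `crop_value`.
#' @export
ligand_rmsd_trace <- function(traj, ligand, align = NULL, reference = 1L,
                              crop_threshold = NULL, crop_value = 10) {
  stopifnot(inherits(traj, "Trajectory"))
  if (length(ligand) == 0) stop("selection error: empty ligand selection")
  if (max(ligand) > nrow(traj$topology))
    stop("selection error: ligand atoms missing from the topology")
  if (is.null(align)) align <- select_calpha(traj$topology)
  ref <- .resolve_reference(traj, reference)
  nf <- n_frames(traj)
  raw <- numeric(nf)
  for (i in seq_len(nf)) {
    fr <- .align_frame(frame_coords(traj, i), ref, align)
    raw[i] <- .rmsd_xyz(fr[ligand, , drop = FALSE],
                        ref[ligand, , drop = FALSE])
  }
  cropped <- if (is.null(crop_threshold)) rep(FALSE, nf) else raw > crop_threshold
  val <- raw
  val[cropped] <- crop_value
  structure(data.frame(frame = seq_len(nf), time_ns = frame_times(traj),
                       rmsd = val, raw_rmsd = raw, cropped = cropped),
            crop_threshold = crop_threshold, crop_value = crop_value,
            class = c("RmsdTrace", "data.frame"))
}

#' The published crop preset for agonist-unbinding traces
#'
#' Raw RMSD values above 60 Angstrom (free diffusion after leaving the
#' binding pocket) are stored as 10 Angstrom for ease of comparison.
#' @return list(crop_threshold = 60, crop_value = 10).
#' @export
crop_preset_unbinding <- function() list(crop_threshold = 60, crop_value = 10)

#' Ligand displacement along the pore axis
#'
#' Signed z-displacement of the ligand centre of mass relative to the first
#' frame, in the axis frame produced by [align_pore_axis()] (+z points toward
#' the outer membrane leaflet / extracellular side, so positive values are
#' movement toward the outer leaflet).
#'
#' @param traj an axis-aligned `Trajectory`.
#' @param ligand `Selection` of ligand atoms.
#' @return object of class `ZTrace`: data frame (frame, time_ns, dz).
#' @export
ligand_z_trace <- function(traj, ligand) {
  stopifnot(inherits(traj, "Trajectory"), length(ligand) > 0)
  nf <- n_frames(traj)
  m <- atom_masses(traj$topology)[ligand]
  zc <- vapply(seq_len(nf), function(i) {
    fr <- traj$coords[ligand, 3, i]
    sum(fr * m) / sum(m)
  }, numeric(1))
  structure(data.frame(frame = seq_len(nf), time_ns = frame_times(traj),
                       dz = zc - zc[1]),
            class = c("ZTrace", "data.frame"))
}

#' Pairwise ligand RMSD matrix after reference alignment
#'
#' Every frame is aligned to the reference via the alignment selection (one
#' superposition per frame, matching the RMSD-trace definition); the pairwise
#' ligand RMSD is then the Euclidean distance between flattened ligand
#' coordinate vectors divided by sqrt(number of atoms).
#'
#' @inheritParams ligand_rmsd_trace
#' @return symmetric n_frames x n_frames matrix, Angstrom.
#' @export
ligand_rmsd_matrix <- function(traj, ligand, align = NULL, reference = 1L) {
  stopifnot(inherits(traj, "Trajectory"), length(ligand) > 0)
  if (is.null(align)) align <- select_calpha(traj$topology)
  ref <- .resolve_reference(traj, reference)
  nf <- n_frames(traj)
  L <- length(ligand)
  M <- matrix(NA_real_, nf, 3 * L)
  for (i in seq_len(nf)) {
    fr <- .align_frame(frame_coords(traj, i), ref, align)
    M[i, ] <- as.numeric(fr[ligand, , drop = FALSE])
  }
  as.matrix(stats::dist(M)) / sqrt(L)
}

#' Quality-threshold pose clustering of trajectory frames
#'
#' Greedy QT-style clustering on the pairwise ligand RMSD matrix: repeatedly
#' extract, among unassigned frames, the frame whose cutoff-neighbourhood
#' (unassigned frames within `cutoff`) is largest, as a new cluster, until
#' `max_clusters` clusters exist or every frame is assigned. Remaining frames
#' are labelled noise (cluster 0). Ties are broken by lowest frame index, so
#' the partition is deterministic and permutation-stable. Defaults follow the
#' published analysis: 10 clusters, 1 Angstrom cutoff.
#'
#' @inheritParams ligand_rmsd_trace
#' @param cutoff RMSD cutoff, Angstrom (default 1.0).
#' @param max_clusters maximum number of clusters to extract (default 10).
#' @return object of class `ClusterResult`: list with `labels` (per-frame
#'   integer, 0 = noise), `populations` (per-cluster frame counts, extraction
#'   order), `representatives` (medoid frame index per cluster), `cutoff`,
#'   `max_clusters`.
#' @export
cluster_poses <- function(traj, ligand, align = NULL, cutoff = 1.0,
                          max_clusters = 10L, reference = 1L) {
  if (cutoff <= 0) stop("parameter error: cutoff must be positive")
  nf <- n_frames(traj)
  if (nf < 2) stop("need at least 2 frames to cluster")
  D <- ligand_rmsd_matrix(traj, ligand, align, reference)
  labels <- integer(nf)
  cl <- 0L
  unassigned <- rep(TRUE, nf)
  populations <- integer(0)
  representatives <- integer(0)
  while (any(unassigned) && cl < max_clusters) {
    # neighbourhood sizes among unassigned frames (a frame neighbours itself)
    nn <- sapply(which(unassigned), function(i)
      sum(unassigned & D[i, ] <= cutoff))
    cand <- which(unassigned)
    centre <- cand[which.max(nn)]  # first max = lowest frame index
    members <- cand[D[centre, cand] <= cutoff]
    cl <- cl + 1L
    labels[members] <- cl
    unassigned[members] <- FALSE
    populations <- c(populations, length(members))
    # medoid: member minimising summed RMSD to the other members
    med <- members[which.min(rowSums(D[members, members, drop = FALSE]))]
    representatives <- c(representatives, med)
  }
  structure(list(labels = labels, populations = populations,
                 representatives = representatives, cutoff = cutoff,
                 max_clusters = as.integer(max_clusters)),
            class = "ClusterResult")
}

#' @export
print.ClusterResult <- function(x, ...) {
  cat(sprintf("ClusterResult: %d clusters over %d frames (cutoff %g A)\n",
              length(x$populations), length(x$labels), x$cutoff))
  cat("populations:", paste(x$populations, collapse = ", "),
      "| noise:", sum(x$labels == 0L), "\n")
  invisible(x)
}

#' Export cluster representatives as a multi-model PDB
#' @param traj the clustered `Trajectory`.
#' @param result a `ClusterResult`.
#' @param path output PDB path.
#' @param top number of clusters to export (default 5, extraction order).
#' @return `path`, invisibly.
#' @export
write_representatives <- function(traj, result, path, top = 5L) {
  stopifnot(inherits(result, "ClusterResult"))
  reps <- head(result$representatives, top)
  sub <- as_trajectory(traj$topology,
                       traj$coords[, , reps, drop = FALSE],
                       frame_interval = traj$frame_interval)
  write_trajectory(sub, path)
}
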
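#' Pore hydration: waters near the activation gate
#'
#' Counts, per frame, the distinct water molecules whose oxygen lies within
#' `cutoff` of any atom of the gate selection. The gate defaults to all atoms
#' of the five 9-prime leucine residues (the hydrophobic activation gate);
#' water identity is tracked by residue, so a molecule straddling the cutoff
#' with several atoms counts once. Distances are plain Euclidean (inputs are
#' expected to be whole-molecule frames; no periodic imaging).
#'
#' @param traj a `Trajectory`.
#' @param gate `Selection` of gate atoms; default: all atoms of the 9' ring
#'   residues from `prime_map`.
#' @param prime_map `PrimeMap` used only when `gate` is NULL.
#' @param water_resnames residue names recognised as water.
#' @param cutoff distance cutoff, Angstrom (default 3.0).
#' @return object of class `HydrationTrace`: data frame (frame, time_ns,
#'   count); attributes `cutoff`, `gate_expr`.
#' @export
hydration_count <- function(traj, gate = NULL, prime_map = NULL,
                            water_resnames = .water_resnames, cutoff = 3.0) {
  stopifnot(inherits(traj, "Trajectory"))
  top <- traj$topology
  if (is.null(gate)) {
    if (is.null(prime_map))
      stop("supply either a gate selection or a prime_map")
    gate <- select_prime_ring(top, prime_map, 9L)
  }
  if (length(gate) == 0) stop("empty gate selection")
  wat <- which(top$resid %in% water_resnames & top$element == "O")
  nf <- n_frames(traj)
  if (length(wat) == 0) {
    warning("no waters in topology; returning all-zero hydration trace")
    return(structure(data.frame(frame = seq_len(nf),
                                time_ns = frame_times(traj), count = 0L),
                     cutoff = cutoff, gate_expr = attr(gate, "expr"),
                     class = c("HydrationTrace", "data.frame")))
  }
  wkey <- paste(top$chain[wat], top$resno[wat], sep = ":")
  cut2 <- cutoff^2
  counts <- integer(nf)
  for (i in seq_len(nf)) {
    fr <- traj$coords[, , i]
    G <- fr[gate, , drop = FALSE]
    W <- fr[wat, , drop = FALSE]
    mind2 <- rep(Inf, nrow(W))
    for (j in seq_len(nrow(G))) {
      d2 <- (W[, 1] - G[j, 1])^2 + (W[, 2] - G[j, 2])^2 +
        (W[, 3] - G[j, 3])^2
      sel <- d2 < mind2
      mind2[sel] <- d2[sel]
    }
    counts[i] <- length(unique(wkey[mind2 <= cut2]))
  }
  structure(data.frame(frame = seq_len(nf), time_ns = frame_times(traj),
                       count = counts),
            cutoff = cutoff, gate_expr = attr(gate, "expr"),
            class = c("HydrationTrace", "data.frame"))
}

#' Upper-ECD spread over a trajectory
#'
#' After least-squares alignment of each frame onto the first frame using all
#' protein C-alpha atoms, computes per frame either
#' \describe{
#'   \item{radial_spread}{the mean, over the five subunits, of the distance
#'     from each subunit's upper-ECD centre of mass to the centroid of the
#'     five centres (the default reported mode; contraction of the upper ECD
#'     lowers it), or}
#'   \item{com_displacement}{the mean over subunits of the displacement of
#'     each upper-ECD centre of mass from its first-frame position.}
#' }
#' Both modes ship because "spread" admits either reading; the mode is
#' recorded in the result. Residues missing from a subunit are tolerated
#' (the used subset is recorded); a subunit contributing no atoms is an
#' error naming the chain.
#'
#' @param traj a `Trajectory`.
#' @param ranges an `EcdRanges` (per-class residue intervals).
#' @param subunits a `SubunitMap`.
#' @param mode `"radial_spread"` or `"com_displacement"`.
#' @param align align each frame on protein C-alpha atoms first (default
#'   TRUE).
#' @param mass_weighted mass-weight the centres of mass (default TRUE).
#' @return object of class `SpreadTrace`: data frame (frame, time_ns, value);
#'   attributes `mode`, `residues_used` (per-chain counts).
#' @export
ecd_spread <- function(traj, ranges, subunits,
                       mode = c("radial_spread", "com_displacement"),
                       align = TRUE, mass_weighted = TRUE) {
  mode <- match.arg(mode)
  stopifnot(inherits(traj, "Trajectory"), inherits(ranges, "EcdRanges"),
            inherits(subunits, "SubunitMap"))
  top <- traj$topology
  sel <- list()
  for (i in seq_len(nrow(subunits))) {
    ch <- subunits$chain[i]; cl <- subunits$class[i]
    if (is.null(ranges[[cl]])) stop("no upper-ECD ranges for class ", cl)
    rn <- unlist(apply(ranges[[cl]], 1, function(r) r[1]:r[2],
                       simplify = FALSE))
    idx <- select_atoms(top, chain = ch, resno = rn)
    if (length(idx) == 0)
      stop("chain ", ch, ": no atoms resolved in the upper-ECD ranges")
    sel[[ch]] <- idx
  }
  ca <- select_calpha(top)
  masses <- atom_masses(top)
  if (!mass_weighted) masses <- rep(1, length(masses))
  ref <- frame_coords(traj, 1)
  nf <- n_frames(traj)
  com0 <- NULL
  value <- numeric(nf)
  for (i in seq_len(nf)) {
    fr <- frame_coords(traj, i)
    if (align && length(ca) >= 3) fr <- .align_frame(fr, ref, ca)
    coms <- t(vapply(sel, function(idx) {
      m <- masses[idx]
      colSums(fr[idx, , drop = FALSE] * m) / sum(m)
    }, numeric(3)))
    if (i == 1) com0 <- coms
    value[i] <- switch(mode,
      radial_spread = {
        ctr <- colMeans(coms)
        mean(sqrt(rowSums(sweep(coms, 2, ctr)^2)))
      },
      com_displacement = mean(sqrt(rowSums((coms - com0)^2))))
  }
  structure(data.frame(frame = seq_len(nf), time_ns = frame_times(traj),
                       value = value),
            mode = mode,
            residues_used = vapply(sel, function(idx)
              length(unique(top$resno[idx])), integer(1)),
            class = c("SpreadTrace", "data.frame"))
}

#' Kernel-density export of a trace for violin-style plotting
#' @param x numeric vector (e.g. a trace column).
#' @param n grid size (default 128).
#' @return data frame (value, density).
#' @export
trace_density <- function(x, n = 128) {
  d <- stats::density(x, n = n)
  data.frame(value = d$x, density = d$y)
}
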
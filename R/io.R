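#' Read an atomic structure from PDB or mmCIF
#'
#' Parses a coordinate file into a [as_structure()] atom table. Parsing of the
#' standard formats is delegated to \pkg{bio3d}; author-assigned residue
#' numbering is kept for all user-facing selections. When several alternate
#' locations are present, the highest-occupancy altloc is kept (ties broken
#' alphabetically) so that downstream geometry sees a single conformer.
#'
#' @param path file path.
#' @param format `"pdb"`, `"mmcif"` or `"auto"` (by extension; `.cif` is
#'   mmCIF, anything else PDB).
#' @param model 1-based model number to extract from multi-model files.
#' @return a `Structure`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"), model = 1L) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  parsed <- tryCatch(
    if (format == "mmcif") bio3d::read.cif(path, verbose = FALSE)
    else suppressWarnings(bio3d::read.pdb(path, multi = (model > 1L),
                                          rm.alt = FALSE, verbose = FALSE)),
    error = function(e) stop("cannot parse ", path, " as ", format, ": ",
                             conditionMessage(e), call. = FALSE))
  at <- parsed$atom
  if (is.null(at) || nrow(at) == 0L) stop("empty model in ", path)
  if (model > 1L) {
    if (is.null(parsed$xyz) || nrow(parsed$xyz) < model)
      stop("model ", model, " not present in ", path)
    m <- matrix(parsed$xyz[model, ], ncol = 3, byrow = TRUE)
    at$x <- m[, 1]; at$y <- m[, 2]; at$z <- m[, 3]
  }
  s <- as_structure(data.frame(
    chain = .blank(at$chain), resno = at$resno, insert = .blank(at$insert),
    resid = .blank(at$resid), elety = .blank(at$elety),
    element = if ("elesy" %in% names(at)) .blank(at$elesy) else "",
    x = at$x, y = at$y, z = at$z, altloc = .blank(at$alt),
    occ = ifelse(is.na(at$o), 1, at$o), b = ifelse(is.na(at$b), 0, at$b),
    stringsAsFactors = FALSE), model_id = model)
  collapse_altloc(s)
}

#' Collapse alternate locations to a single conformer
#'
#' Keeps, within each (chain, resno, insert, atom name) group, the altloc with
#' the highest occupancy; ties are broken alphabetically by altloc identifier.
#' @param s a `Structure`.
#' @return a `Structure` with at most one row per atom site.
#' @export
collapse_altloc <- function(s) {
  if (!any(nzchar(s$altloc))) return(s)
  key <- paste(s$chain, s$resno, s$insert, s$elety, sep = "\r")
  ord <- order(key, -s$occ, s$altloc)
  keep <- ord[!duplicated(key[ord])]
  out <- s[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "model_id") <- attr(s, "model_id")
  class(out) <- class(s)
  out
}

.pdb_atom_line <- function(type, serial, elety, altloc, resid, chain, resno,
                           insert, x, y, z, occ, b, element) {
  name4 <- ifelse(nchar(elety) >= 4, substr(elety, 1, 4),
                  sprintf("%-3s", elety))
  name4 <- ifelse(nchar(name4) == 4, name4, paste0(" ", name4))
  sprintf("%-6s%5d %4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          type, serial %% 100000L, name4, substr(paste0(altloc, " "), 1, 1),
          substr(resid, 1, 3), substr(paste0(chain, " "), 1, 1), resno,
          substr(paste0(insert, " "), 1, 1), x, y, z, occ, b, element)
}

.structure_pdb_lines <- function(s, xyz = NULL) {
  if (is.null(xyz)) xyz <- coords(s)
  type <- ifelse(s$resid %in% .standard_aa, "ATOM", "HETATM")
  .pdb_atom_line(type, seq_len(nrow(s)), s$elety, s$altloc, s$resid, s$chain,
                 s$resno, s$insert, xyz[, 1], xyz[, 2], xyz[, 3], s$occ, s$b,
                 s$element)
}

#' Write a Structure to a PDB file
#' @param s a `Structure`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path) {
  stopifnot(inherits(s, "Structure"))
  writeLines(c(.structure_pdb_lines(s), "END"), path)
  invisible(path)
}

#' Construct a Trajectory
#'
#' A `Trajectory` couples a topology `Structure` with an ordered stack of
#' coordinate frames (one position per topology atom per frame) and the frame
#' sampling interval in nanoseconds (default 0.4 ns).
#'
#' @param topology a `Structure`.
#' @param frames 3-d array `(atom, xyz, frame)` or list of n x 3 matrices.
#' @param frame_interval sampling interval between stored frames, ns.
#' @return object of class `Trajectory`.
#' @export
as_trajectory <- function(topology, frames, frame_interval = 0.4) {
  stopifnot(inherits(topology, "Structure"), frame_interval > 0)
  if (is.list(frames))
    frames <- array(unlist(frames), dim = c(nrow(frames[[1]]), 3, length(frames)))
  stopifnot(is.array(frames), length(dim(frames)) == 3)
  if (dim(frames)[1] != nrow(topology) || dim(frames)[2] != 3)
    stop("each frame must supply one xyz position per topology atom")
  if (!all(is.finite(frames))) stop("non-finite coordinates in frames")
  structure(list(topology = topology, coords = frames,
                 frame_interval = frame_interval),
            class = "Trajectory")
}

#' @export
print.Trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d frames x %d atoms, dt = %g ns\n",
              n_frames(x), nrow(x$topology), x$frame_interval))
  invisible(x)
}

#' Number of frames in a Trajectory
#' @param traj a `Trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Coordinates of one frame
#' @param traj a `Trajectory`.
#' @param i 1-based frame index.
#' @return n x 3 coordinate matrix.
#' @export
frame_coords <- function(traj, i) traj$coords[, , i, drop = TRUE]

#' Frame times of a Trajectory
#' @param traj a `Trajectory`.
#' @return numeric vector, ns, starting at 0 for the first stored frame.
#' @export
frame_times <- function(traj) (seq_len(n_frames(traj)) - 1) * traj$frame_interval

#' Read a trajectory from a multi-model PDB file
#'
#' Multi-model PDB is the package's required interchange dialect for
#' trajectories; frames are returned in storage order. All models must share
#' one atom list.
#'
#' @param path multi-model PDB file.
#' @param topology optional `Structure` to validate the atom count against.
#' @param frame_interval sampling interval, ns (default 0.4).
#' @return a `Trajectory`.
#' @export
read_trajectory <- function(path, topology = NULL, frame_interval = 0.4) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  is_atom <- grepl("^(ATOM|HETATM)", lines)
  model_id <- cumsum(grepl("^MODEL", lines))
  if (any(model_id > 0)) {
    per_model <- table(model_id[is_atom & model_id > 0])
    if (length(unique(per_model)) > 1)
      stop("topology error: models in ", path, " disagree on atom count (",
           paste(unique(per_model), collapse = " vs "), ")")
  }
  parsed <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                     error = function(e)
                       stop("topology error reading ", path, ": ",
                            conditionMessage(e), call. = FALSE))
  top <- as_structure(data.frame(
    chain = .blank(parsed$atom$chain), resno = parsed$atom$resno,
    insert = .blank(parsed$atom$insert), resid = .blank(parsed$atom$resid),
    elety = .blank(parsed$atom$elety),
    element = if ("elesy" %in% names(parsed$atom)) .blank(parsed$atom$elesy) else "",
    x = parsed$atom$x, y = parsed$atom$y, z = parsed$atom$z,
    altloc = .blank(parsed$atom$alt),
    occ = ifelse(is.na(parsed$atom$o), 1, parsed$atom$o),
    b = ifelse(is.na(parsed$atom$b), 0, parsed$atom$b),
    stringsAsFactors = FALSE))
  xyz <- parsed$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  if (ncol(xyz) != 3 * nrow(top))
    stop("topology error: models in ", path, " disagree on atom count")
  if (!is.null(topology) && nrow(topology) != nrow(top))
    stop("topology error: file has ", nrow(top), " atoms, topology has ",
         nrow(topology))
  nf <- nrow(xyz)
  frames <- array(NA_real_, dim = c(nrow(top), 3, nf))
  for (i in seq_len(nf))
    frames[, , i] <- matrix(xyz[i, ], ncol = 3, byrow = TRUE)
  as_trajectory(if (is.null(topology)) top else topology, frames,
                frame_interval = frame_interval)
}

#' Write a Trajectory as a multi-model PDB file
#' @param traj a `Trajectory`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "Trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(n_frames(traj))) {
    writeLines(sprintf("MODEL %8d", i), con)
    writeLines(.structure_pdb_lines(traj$topology, frame_coords(traj, i)), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
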
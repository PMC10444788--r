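#' Rigid-body transform
#'
#' @param rotation 3 x 3 rotation matrix (orthonormal, det +1).
#' @param translation length-3 translation vector, Angstrom.
#' @return object of class `RigidTransform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  stopifnot(is.matrix(rotation), all(dim(rotation) == c(3, 3)),
            length(translation) == 3)
  if (abs(det(rotation) - 1) > 1e-6 ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-6)
    stop("rotation must be orthonormal with determinant +1")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "RigidTransform")
}

#' Apply a rigid transform to coordinates
#' @param xyz n x 3 coordinate matrix, or a `Structure`.
#' @param tr a `RigidTransform`.
#' @return transformed coordinates (same type as the input).
#' @export
apply_transform <- function(xyz, tr) {
  stopifnot(inherits(tr, "RigidTransform"))
  if (inherits(xyz, "Structure"))
    return(set_coords(xyz, apply_transform(coords(xyz), tr)))
  sweep(xyz %*% t(tr$rotation), 2, -tr$translation)
}

#' Compose two rigid transforms (apply `a` first, then `b`)
#' @param a,b `RigidTransform` objects.
#' @return a `RigidTransform` equivalent to `b(a(x))`.
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(b$rotation %*% a$rotation,
                  as.numeric(b$rotation %*% a$translation) + b$translation)
}

.kabsch <- function(P, Q) {
  # returns rotation R and translation t minimising ||R P + t - Q||
  pc <- colMeans(P); qc <- colMeans(Q)
  Pc <- sweep(P, 2, pc); Qc <- sweep(Q, 2, qc)
  H <- crossprod(Pc, Qc)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(rotation = R, translation = as.numeric(qc - R %*% pc),
       sing = s$d)
}

.rmsd_xyz <- function(A, B) sqrt(mean(rowSums((A - B)^2)))

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the rigid-body transform minimising the RMSD between paired atoms of
#' a mobile and a reference structure, via singular value decomposition of the
#' covariance of the centred coordinate pairs.
#'
#' @param mobile,reference `Structure` objects (or n x 3 coordinate matrices).
#' @param sel_mobile,sel_reference paired atom selections (equal length;
#'   `sel_reference` defaults to `sel_mobile`). Ignored when raw matrices are
#'   given.
#' @return list with `transform` (a `RigidTransform` taking mobile onto the
#'   reference), `rmsd` (Angstrom, at the optimum) and `n` (atom pairs used).
#' @export
superpose <- function(mobile, reference, sel_mobile = NULL,
                      sel_reference = sel_mobile) {
  P <- if (inherits(mobile, "Structure")) coords(mobile) else as.matrix(mobile)
  Q <- if (inherits(reference, "Structure")) coords(reference) else as.matrix(reference)
  if (!is.null(sel_mobile)) P <- P[sel_mobile, , drop = FALSE]
  if (!is.null(sel_reference)) Q <- Q[sel_reference, , drop = FALSE]
  if (nrow(P) != nrow(Q))
    stop("paired selections must have equal length (", nrow(P), " vs ",
         nrow(Q), ")")
  if (nrow(P) < 3) stop("geometry error: need at least 3 paired atoms")
  k <- .kabsch(P, Q)
  if (k$sing[2] < 1e-8 * max(k$sing[1], 1))
    stop("geometry error: paired atoms are (near-)collinear")
  tr <- rigid_transform(k$rotation, k$translation)
  list(transform = tr, rmsd = .rmsd_xyz(apply_transform(P, tr), Q), n = nrow(P))
}

#' RMSD between two coordinate sets without fitting
#' @param A,B n x 3 coordinate matrices.
#' @return root-mean-square deviation, Angstrom.
#' @export
rmsd_coords <- function(A, B) {
  stopifnot(nrow(A) == nrow(B))
  .rmsd_xyz(as.matrix(A), as.matrix(B))
}

#' Random rotation matrix (uniform over SO(3))
#' @param n ignored; one matrix is returned.
#' @return 3 x 3 rotation matrix.
#' @keywords internal
random_rotation <- function(n = 1) {
  M <- matrix(rnorm(9), 3, 3)
  qr_ <- qr(M)
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
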
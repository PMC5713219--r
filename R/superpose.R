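# Optimal rigid-body superposition (Kabsch) and plain coordinate RMSD.

#' Plain RMSD between two coordinate sets (no fitting)
#' @param a,b numeric N x 3 matrices.
#' @return RMSD in Angstrom.
#' @export
coord_rmsd <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) stop("coordinate sets differ in size")
  sqrt(sum((a - b)^2) / nrow(a))
}

#' Least-squares rigid superposition of two point sets
#'
#' Finds the proper rotation and translation minimising the RMSD of
#' `mobile` onto `reference` (SVD of the cross-covariance; if the optimal
#' orthogonal transform is a reflection, the smallest singular direction is
#' flipped so a proper rotation is always returned).
#'
#' @param mobile,reference numeric N x 3 matrices with matching rows
#'   (N >= 1; N >= 3 for a unique rotation).
#' @return list with `coords` (mobile after superposition), `rmsd`,
#'   `rotation` (3 x 3, det +1) and `translation` such that
#'   `coords = mobile %*% rotation + translation` (row-vector convention).
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference)) {
    stop("mobile and reference have different point counts (",
         nrow(mobile), " vs ", nrow(reference), ")")
  }
  if (nrow(mobile) < 1) stop("need at least one point")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  p <- sweep(mobile, 2, cm); q <- sweep(reference, 2, cr)
  h <- crossprod(p, q)           # 3x3 cross-covariance
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1             # degenerate (rank-deficient) point sets
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rot <- t(rot)                  # row-vector convention: x' = x %*% rot
  coords <- sweep(p %*% rot, 2, cr, FUN = "+")
  list(coords = coords,
       rmsd = coord_rmsd(coords, reference),
       rotation = rot,
       translation = cr - cm %*% rot)
}

#' Superpose every frame of a trajectory onto a reference
#'
#' The fit is computed on `selection` and applied to all atoms of the frame.
#'
#' @param traj an [md_trajectory()].
#' @param reference N x 3 reference coordinates for the selection, an
#'   [md_structure()], or `NULL` for frame 1 of `traj`.
#' @param selection integer atom indices used for the fit (default: all).
#' @return a new `md_trajectory` with superposed coordinates.
#' @export
superpose_trajectory <- function(traj, reference = NULL, selection = NULL) {
  if (is.null(selection)) selection <- seq_len(n_atoms(traj))
  selection <- check_selection(traj, selection)
  ref <- .reference_coords(traj, reference, selection)
  out <- traj$xyz
  for (f in seq_len(n_frames(traj))) {
    all_xyz <- frame_coords(traj, f)
    fit <- kabsch_superpose(all_xyz[selection, , drop = FALSE], ref)
    moved <- sweep(all_xyz %*% fit$rotation, 2, as.vector(fit$translation),
                   FUN = "+")
    out[f, ] <- as.vector(t(moved))
  }
  md_trajectory(traj$topology, out, frame_interval = traj$frame_interval)
}

.reference_coords <- function(traj, reference, selection) {
  if (is.null(reference)) {
    frame_coords(traj, 1, selection)
  } else if (inherits(reference, "md_structure")) {
    structure_coords(reference, selection)
  } else if (inherits(reference, "md_trajectory")) {
    frame_coords(reference, 1, selection)
  } else {
    ref <- as.matrix(reference)
    if (nrow(ref) == length(selection)) ref else ref[selection, , drop = FALSE]
  }
}
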
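# Dynamic cross-correlation matrix and essential-dynamics PCA.
#
# The DCCM entry for residues i, j is the normalised covariance of their
# 3-D displacement vectors,
#   X_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2><|dr_j|^2>),  dr_i = r_i - <r_i>,
# i.e. the numerator is the displacement dot product, not a per-component
# correlation. The PCA operates on the 3N x 3N Cartesian covariance of the
# selected sites.

#' Dynamic cross-correlation matrix
#'
#' @param traj an [md_trajectory()].
#' @param selection integer atom indices (typically one C-alpha per residue,
#'   see [select_calpha()]); default all atoms.
#' @param window frame window (`NULL`, `c(start, end)`, or index vector).
#' @param superpose fit frames onto the window-mean structure before
#'   computing displacements (default `TRUE`; disable for trajectories that
#'   already share a frame of reference).
#' @return a `dccm_matrix`: symmetric N x N matrix with unit diagonal and
#'   entries in [-1, 1], residue labels as dimnames. Zero-variance residues
#'   get 0 off-diagonal entries (diagonal 1) with a warning.
#' @export
dccm <- function(traj, selection = NULL, window = NULL, superpose = TRUE) {
  if (is.null(selection)) selection <- seq_len(n_atoms(traj))
  selection <- check_selection(traj, selection)
  window <- .resolve_window(traj, window)
  if (length(window) < 2) stop("need at least 2 frames for a DCCM")
  arr <- .window_coords(traj, selection, window, superpose)
  n <- length(selection)
  mean_xyz <- apply(arr, c(2, 3), mean)
  # covariance of displacement vectors: sum over x, y, z of per-axis products
  num <- matrix(0, n, n)
  for (k in 1:3) {
    d <- arr[, , k] - matrix(mean_xyz[, k], length(window), n, byrow = TRUE)
    num <- num + crossprod(d) / length(window)
  }
  v <- diag(num)
  zero <- v <= .Machine$double.eps * max(v, 1)
  if (any(zero)) {
    warning(sum(zero), " zero-variance residue(s); their correlations are ",
            "reported as 0")
  }
  denom <- sqrt(outer(pmax(v, .Machine$double.xmin),
                      pmax(v, .Machine$double.xmin)))
  x <- num / denom
  x[zero, ] <- 0
  x[, zero] <- 0
  diag(x) <- 1
  x <- pmin(pmax(x, -1), 1)
  labels <- residue_labels(traj$topology, selection)
  dimnames(x) <- list(labels, labels)
  class(x) <- c("dccm_matrix", class(x))
  x
}

#' Zero out weak correlations
#'
#' Entries with `|X| < cutoff` are set to 0 (the diagonal is untouched),
#' matching the convention of neglecting correlated motions below a
#' magnitude threshold when displaying or analysing a DCCM.
#'
#' @param m a DCCM (matrix).
#' @param cutoff magnitude threshold in [0, 1] (default 0.3).
#' @return matrix of the same shape.
#' @export
threshold_dccm <- function(m, cutoff = 0.3) {
  if (cutoff < 0 || cutoff > 1) stop("cutoff must be in [0, 1]")
  d <- diag(m)
  m[abs(m) < cutoff] <- 0
  diag(m) <- d
  m
}

#' Essential-dynamics PCA over Cartesian coordinates
#'
#' Builds the 3N x 3N covariance matrix
#' `Z_ij = <(x_i - <x_i>)(x_j - <x_j>)>` of the selected sites' Cartesian
#' coordinates and eigendecomposes it.
#'
#' @inheritParams dccm
#' @return a `traj_pca` list: `covariance` (3N x 3N), `mean_coords`
#'   (N x 3), `values` (eigenvalues, nonincreasing), `vectors` (orthonormal
#'   columns), `selection`, `labels`.
#' @export
trajectory_pca <- function(traj, selection = NULL, window = NULL,
                           superpose = TRUE) {
  if (is.null(selection)) selection <- seq_len(n_atoms(traj))
  selection <- check_selection(traj, selection)
  window <- .resolve_window(traj, window)
  if (length(window) < 2) stop("need at least 2 frames for PCA")
  arr <- .window_coords(traj, selection, window, superpose)
  f <- length(window); n <- length(selection)
  flat <- matrix(0, f, 3 * n)  # frame rows, (x1,y1,z1,x2,...) columns
  for (t in seq_len(f)) flat[t, ] <- as.vector(t(matrix(arr[t, , ], ncol = 3)))
  mu <- colMeans(flat)
  d <- sweep(flat, 2, mu)
  z <- crossprod(d) / f  # population covariance
  ev <- eigen(z, symmetric = TRUE)
  structure(list(covariance = z,
                 mean_coords = matrix(mu, ncol = 3, byrow = TRUE),
                 values = ev$values, vectors = ev$vectors,
                 selection = selection,
                 labels = residue_labels(traj$topology, selection)),
            class = "traj_pca")
}

#' @export
print.traj_pca <- function(x, ...) {
  tot <- sum(pmax(x$values, 0))
  cat("traj_pca:", length(x$values), "modes; leading eigenvalues:",
      paste(signif(utils::head(x$values, 3), 4), collapse = ", "),
      sprintf("(PC1 %.1f%% of variance)\n",
              100 * max(x$values[1], 0) / max(tot, .Machine$double.xmin)))
  invisible(x)
}

#' Project trajectory frames onto principal components
#'
#' Frames are centred on the PCA mean structure and dotted with the first
#' `k` eigenvectors.
#'
#' @param traj an [md_trajectory()].
#' @param pca a [trajectory_pca()] result.
#' @param k number of components (default 2).
#' @param window frame window (default: all frames).
#' @param superpose fit each frame onto the PCA mean structure first
#'   (default `TRUE`; use the setting the PCA itself was run with).
#' @return F x k matrix of scores (columns `PC1`, `PC2`, ...).
#' @export
pca_project <- function(traj, pca, k = 2, window = NULL, superpose = TRUE) {
  stopifnot(inherits(pca, "traj_pca"))
  if (k > ncol(pca$vectors)) stop("k exceeds the number of modes")
  selection <- check_selection(traj, pca$selection)
  window <- .resolve_window(traj, window)
  mu <- as.vector(t(pca$mean_coords))
  scores <- matrix(0, length(window), k)
  for (t in seq_along(window)) {
    m <- frame_coords(traj, window[t], selection)
    if (superpose) m <- kabsch_superpose(m, pca$mean_coords)$coords
    scores[t, ] <- (as.vector(t(m)) - mu) %*% pca$vectors[, seq_len(k),
                                                          drop = FALSE]
  }
  colnames(scores) <- paste0("PC", seq_len(k))
  scores
}
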
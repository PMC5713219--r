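# Per-frame RMSD, per-residue RMSF, and windowed summary statistics.

.resolve_window <- function(traj, window) {
  f <- n_frames(traj)
  if (is.null(window)) return(seq_len(f))
  if (length(window) == 2) window <- window[1]:window[2]
  window <- as.integer(window)
  if (length(window) == 0) stop("empty frame window")
  if (any(window < 1) || any(window > f)) stop("window outside 1..", f)
  window
}

#' Per-frame RMSD relative to a reference
#'
#' @param traj an [md_trajectory()].
#' @param reference reference coordinates (see [superpose_trajectory()]);
#'   `NULL` uses frame 1.
#' @param selection integer atom indices the RMSD is computed (and, when
#'   `superpose = TRUE`, fitted) on; default all atoms.
#' @param superpose apply least-squares superposition per frame before the
#'   deviation (default `TRUE`).
#' @return numeric vector, one Angstrom value per frame.
#' @export
rmsd_series <- function(traj, reference = NULL, selection = NULL,
                        superpose = TRUE) {
  if (is.null(selection)) selection <- seq_len(n_atoms(traj))
  selection <- check_selection(traj, selection)
  ref <- .reference_coords(traj, reference, selection)
  if (nrow(ref) != length(selection)) stop("reference/selection mismatch")
  vapply(seq_len(n_frames(traj)), function(f) {
    m <- frame_coords(traj, f, selection)
    if (superpose) kabsch_superpose(m, ref)$rmsd else coord_rmsd(m, ref)
  }, numeric(1))
}

#' Per-residue root-mean-square fluctuation
#'
#' `RMSF_i = sqrt(mean ||r_i - <r_i>||^2)` over the window. When
#' `superpose = TRUE` frames are first fitted onto the window-mean structure
#' (initial fit onto the first window frame, then one refinement pass onto
#' the resulting mean).
#'
#' @param traj an [md_trajectory()].
#' @param selection integer atom indices (one fluctuating site each);
#'   default all atoms.
#' @param window frame window: `NULL` (all), a `c(start, end)` pair, or an
#'   index vector.
#' @param superpose fit frames onto the window-mean structure first.
#' @return numeric vector of Angstrom values, named by residue label.
#' @export
rmsf <- function(traj, selection = NULL, window = NULL, superpose = TRUE) {
  if (is.null(selection)) selection <- seq_len(n_atoms(traj))
  selection <- check_selection(traj, selection)
  window <- .resolve_window(traj, window)
  mats <- .window_coords(traj, selection, window, superpose)
  n <- length(selection)
  f <- length(window)
  devsq <- matrix(0, f, n)
  mean_xyz <- apply(mats, c(2, 3), mean)
  for (t in seq_len(f)) {
    devsq[t, ] <- rowSums((mats[t, , ] - mean_xyz)^2)
  }
  out <- sqrt(colMeans(devsq))
  names(out) <- residue_labels(traj$topology, selection)
  out
}

# window frames as an F x N x 3 array, optionally superposed onto the
# window-mean structure with one refinement pass
.window_coords <- function(traj, selection, window, superpose) {
  f <- length(window)
  n <- length(selection)
  arr <- array(0, c(f, n, 3))
  for (t in seq_len(f)) arr[t, , ] <- frame_coords(traj, window[t], selection)
  if (!superpose || f < 2) return(arr)
  for (pass in 1:2) {
    ref <- if (pass == 1) matrix(arr[1, , ], ncol = 3) else
      matrix(apply(arr, c(2, 3), mean), ncol = 3)
    for (t in seq_len(f)) {
      arr[t, , ] <- kabsch_superpose(matrix(arr[t, , ], ncol = 3), ref)$coords
    }
  }
  arr
}

#' Mean and population SD over a frame window
#'
#' @param series numeric vector (for example an RMSD series).
#' @param start,end 1-based inclusive window bounds; defaults cover the
#'   whole series.
#' @return list with `mean`, `sd` (population, 1/N) and `window`.
#' @export
window_stats <- function(series, start = 1, end = length(series)) {
  if (start > end || end > length(series) || start < 1) {
    stop("invalid window [", start, ", ", end, "] for series of length ",
         length(series))
  }
  x <- series[start:end]
  m <- mean(x)
  list(mean = m, sd = sqrt(mean((x - m)^2)), window = c(start, end))
}

#' Default equilibration burn-in
#'
#' Windowed trajectory statistics conventionally discard the approach to
#' equilibrium; the default drops the first quarter of the frames.
#'
#' @param n_frames total frame count.
#' @param burnin_frac fraction of initial frames to discard (default 0.25).
#' @return integer vector of retained frame indices.
#' @export
equilibrated_window <- function(n_frames, burnin_frac = 0.25) {
  start <- floor(n_frames * burnin_frac) + 1
  start:n_frames
}
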
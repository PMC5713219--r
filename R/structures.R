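# Core containers: static structures, trajectories, atom selections.
#
# An md_structure is a flat atom table (one row per atom, coordinates in
# Angstrom); an md_trajectory couples one topology with an F x 3A coordinate
# matrix in the usual xyz layout (x1, y1, z1, x2, ...), one row per frame.

STANDARD_AA <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"
)

#' Construct a molecular structure
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `resno`, `resname`, `chain`, `insert`, `x`, `y`, `z`. `insert` may be
#'   omitted (defaults to `""`).
#' @param title optional title string.
#' @return An object of class `md_structure`.
#' @export
md_structure <- function(atoms, title = "") {
  required <- c("serial", "name", "element", "resno", "resname", "chain",
                "x", "y", "z")
  missing <- setdiff(required, names(atoms))
  if (length(missing) > 0) {
    stop("atoms table is missing columns: ", paste(missing, collapse = ", "))
  }
  if (nrow(atoms) < 1) stop("a structure needs at least one atom")
  if (!("insert" %in% names(atoms))) atoms$insert <- ""
  atoms$insert[is.na(atoms$insert)] <- ""
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(coords))) stop("non-finite coordinates in structure")
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$name)
  if (anyDuplicated(key)) {
    stop("duplicate (chain, residue, atom name) entries: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  # residues within a chain must appear in nondecreasing order
  for (ch in unique(atoms$chain)) {
    rs <- atoms$resno[atoms$chain == ch]
    if (is.unsorted(rs, strictly = FALSE)) {
      stop("residues out of order in chain ", ch)
    }
  }
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, title = title), class = "md_structure")
}

#' @export
print.md_structure <- function(x, ...) {
  cat("md_structure:", n_atoms(x), "atoms,",
      length(unique(paste(x$atoms$chain, x$atoms$resno, x$atoms$insert))),
      "residues, chains:",
      paste(unique(x$atoms$chain), collapse = " "), "\n")
  invisible(x)
}

#' Construct a trajectory
#'
#' @param topology an [md_structure()].
#' @param xyz numeric matrix, frames x (3 * n_atoms), columns in
#'   (x1, y1, z1, x2, ...) order. A bare vector is treated as one frame.
#' @param frame_interval time per frame in arbitrary units (default 1).
#' @return An object of class `md_trajectory`.
#' @export
md_trajectory <- function(topology, xyz, frame_interval = 1) {
  stopifnot(inherits(topology, "md_structure"))
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L * n_atoms(topology)) {
    stop("xyz has ", ncol(xyz), " columns; expected ",
         3L * n_atoms(topology), " for ", n_atoms(topology), " atoms")
  }
  if (nrow(xyz) < 1) stop("a trajectory needs at least one frame")
  if (!all(is.finite(xyz))) stop("non-finite coordinates in trajectory")
  structure(list(topology = topology, xyz = xyz,
                 frame_interval = frame_interval),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat("md_trajectory:", n_frames(x), "frames x", n_atoms(x$topology),
      "atoms (frame interval", x$frame_interval, ")\n")
  invisible(x)
}

#' Number of atoms in a structure or trajectory
#' @param x an `md_structure` or `md_trajectory`.
#' @export
n_atoms <- function(x) {
  if (inherits(x, "md_trajectory")) x <- x$topology
  nrow(x$atoms)
}

#' Number of frames in a trajectory
#' @param x an `md_trajectory`.
#' @export
n_frames <- function(x) nrow(x$xyz)

#' xyz column indices for atom indices
#' @param idx integer atom indices (1-based).
#' @return integer vector of columns into an xyz matrix.
#' @export
atom2xyz <- function(idx) as.vector(rbind(3 * idx - 2, 3 * idx - 1, 3 * idx))

#' Coordinates of one frame as an A x 3 matrix
#' @param traj an `md_trajectory`.
#' @param frame frame index (1-based).
#' @param selection optional integer atom indices.
#' @export
frame_coords <- function(traj, frame, selection = NULL) {
  v <- traj$xyz[frame, ]
  m <- matrix(v, ncol = 3, byrow = TRUE)
  if (!is.null(selection)) m <- m[selection, , drop = FALSE]
  colnames(m) <- c("x", "y", "z")
  m
}

#' Coordinates of a static structure as an A x 3 matrix
#' @param structure an `md_structure`.
#' @param selection optional integer atom indices.
#' @export
structure_coords <- function(structure, selection = NULL) {
  m <- as.matrix(structure$atoms[, c("x", "y", "z")])
  if (!is.null(selection)) m <- m[selection, , drop = FALSE]
  m
}

#' Wrap a static structure as a one-frame trajectory
#' @param structure an `md_structure`.
#' @export
as_trajectory <- function(structure) {
  md_trajectory(structure, as.vector(t(structure_coords(structure))))
}

check_selection <- function(x, indices) {
  na <- n_atoms(x)
  if (length(indices) == 0) stop("empty selection")
  if (is.unsorted(indices, strictly = TRUE)) {
    stop("selection indices must be strictly increasing")
  }
  if (any(indices < 1) || any(indices > na)) {
    stop("selection index out of range (1..", na, ")")
  }
  as.integer(indices)
}

#' Select C-alpha atoms
#'
#' Returns indices of `CA` atoms of standard amino-acid residues (one per
#' residue, in residue order); het groups such as bound nucleotides are
#' excluded. A residue carrying zero or multiple `CA` atoms (for example an
#' uncollapsed altloc) is an error.
#'
#' @param structure an `md_structure`.
#' @param chains optional character vector restricting to these chain ids.
#' @return integer atom indices (a Selection).
#' @export
select_calpha <- function(structure, chains = NULL) {
  at <- structure$atoms
  keep <- at$resname %in% STANDARD_AA
  if (!is.null(chains)) keep <- keep & at$chain %in% chains
  at_idx <- which(keep)
  if (length(at_idx) == 0) stop("no standard amino-acid atoms in selection")
  rid <- paste(at$chain[at_idx], at$resno[at_idx], at$insert[at_idx])
  ca <- integer(0)
  for (r in unique(rid)) {
    rows <- at_idx[rid == r]
    hit <- rows[at$name[rows] == "CA"]
    if (length(hit) != 1) {
      stop("residue ", at$resname[rows[1]], " ", sub(" $", "", r), " has ",
           length(hit), " CA atoms (expected exactly 1)")
    }
    ca <- c(ca, hit)
  }
  sort(ca)
}

#' Select atoms by chain and residue range
#' @param structure an `md_structure`.
#' @param chain chain id (single character) or `NULL` for all.
#' @param resno optional integer vector of residue numbers to keep.
#' @param names optional atom-name filter.
#' @return integer atom indices.
#' @export
select_atoms <- function(structure, chain = NULL, resno = NULL, names = NULL) {
  at <- structure$atoms
  keep <- rep(TRUE, nrow(at))
  if (!is.null(chain)) keep <- keep & at$chain %in% chain
  if (!is.null(resno)) keep <- keep & at$resno %in% resno
  if (!is.null(names)) keep <- keep & at$name %in% names
  idx <- which(keep)
  if (length(idx) == 0) stop("selection matched no atoms")
  idx
}

#' Residue labels for a selection
#'
#' One label per selected atom, of the form `"A:GLY2"`.
#'
#' @param structure an `md_structure`.
#' @param selection integer atom indices (default: all atoms).
#' @export
residue_labels <- function(structure, selection = NULL) {
  at <- structure$atoms
  if (is.null(selection)) selection <- seq_len(nrow(at))
  paste0(at$chain[selection], ":", at$resname[selection], at$resno[selection],
         at$insert[selection])
}
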
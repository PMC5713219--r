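# Multi-model PDB input/output. Fixed-column parsing and writing are
# delegated to bio3d; this layer adds the container conversion plus the
# validation bio3d does not enforce (per-model atom counts, altloc collapse
# by occupancy).

#' Read a (multi-model) PDB file or text into a trajectory
#'
#' Each `MODEL`/`ENDMDL` block becomes one frame (a file without `MODEL`
#' records yields a single frame). The topology is taken from the first
#' model. Alternate locations are collapsed to the highest-occupancy copy
#' (ties: first in file). Insertion codes are kept as part of the residue
#' identity.
#'
#' @param input path to a PDB file, or PDB text (detected by an embedded
#'   newline).
#' @param frame_interval time per frame, stored on the trajectory.
#' @return An [md_trajectory()].
#' @export
read_pdb <- function(input, frame_interval = 1) {
  if (length(input) != 1 || !is.character(input)) {
    stop("input must be a single path or PDB text string")
  }
  if (grepl("\n", input, fixed = TRUE)) {
    file <- tempfile(fileext = ".pdb")
    on.exit(unlink(file), add = TRUE)
    writeLines(strsplit(input, "\n", fixed = TRUE)[[1]], file)
  } else {
    file <- input
    if (!file.exists(file)) stop("no such PDB file: ", file)
  }
  lines <- readLines(file)
  .check_model_counts(lines)
  pdb <- bio3d::read.pdb(file, multi = TRUE, verbose = FALSE, rm.alt = FALSE)
  at <- pdb$atom
  xyz <- matrix(pdb$xyz, nrow = nrow(pdb$xyz), ncol = ncol(pdb$xyz))
  if (!all(is.finite(xyz))) stop("unparseable coordinate field in ", file)

  keep <- .collapse_altloc(at)
  at <- at[keep, , drop = FALSE]
  xyz <- xyz[, atom2xyz(keep), drop = FALSE]

  ins <- at$insert
  ins[is.na(ins)] <- ""
  first <- matrix(xyz[1, ], ncol = 3, byrow = TRUE)
  atoms <- data.frame(
    serial = at$eleno, name = at$elety, element = .element_of(at),
    resno = at$resno, resname = at$resid, chain = .chain_of(at),
    insert = ins,
    x = first[, 1], y = first[, 2], z = first[, 3],
    stringsAsFactors = FALSE
  )
  topo <- md_structure(atoms, title = basename(file))
  md_trajectory(topo, xyz, frame_interval = frame_interval)
}

# atom counts must agree across MODEL blocks; bio3d only warns and recycles
.check_model_counts <- function(lines) {
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) <= 1) {
    if (sum(is_atom) == 0) stop("no ATOM/HETATM records found")
    return(invisible(TRUE))
  }
  model_ends <- grep("^ENDMDL", lines)
  if (length(model_ends) != length(model_starts)) {
    stop("unbalanced MODEL/ENDMDL records")
  }
  counts <- mapply(function(s, e) sum(is_atom[s:e]), model_starts, model_ends)
  if (length(unique(counts)) != 1) {
    stop("atom-count mismatch across models: ",
         paste(counts, collapse = ", "))
  }
  invisible(TRUE)
}

.collapse_altloc <- function(at) {
  alt <- at$alt
  alt[is.na(alt)] <- ""
  idx <- seq_len(nrow(at))
  plain <- alt %in% c("", " ")
  if (all(plain)) return(idx)
  occ <- at$o
  occ[is.na(occ)] <- 1
  key <- paste(at$chain, at$resno, at$insert, at$elety)
  keep <- logical(nrow(at))
  for (k in unique(key)) {
    rows <- idx[key == k]
    best <- rows[which.max(occ[rows])]  # ties: first occurrence
    keep[best] <- TRUE
  }
  which(keep)
}

.element_of <- function(at) {
  el <- at$elesy
  bad <- is.na(el) | el == ""
  # fall back on the first letter of the atom name (strip leading digits)
  el[bad] <- substr(gsub("^[0-9]*", "", at$elety[bad]), 1, 1)
  toupper(trimws(el))
}

.chain_of <- function(at) {
  ch <- at$chain
  ch[is.na(ch) | ch == ""] <- "A"
  ch
}

#' Write a structure or trajectory as a (multi-model) PDB file
#'
#' Coordinates are written at standard PDB precision (3 decimals); a
#' multi-frame trajectory produces one `MODEL` block per frame.
#'
#' @param x an [md_structure()] or [md_trajectory()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_pdb <- function(x, file) {
  if (inherits(x, "md_structure")) x <- as_trajectory(x)
  stopifnot(inherits(x, "md_trajectory"))
  at <- x$topology$atoms
  bio3d::write.pdb(
    pdb = NULL, file = file, xyz = x$xyz,
    type = rep("ATOM", nrow(at)),
    resno = at$resno, resid = at$resname, eleno = at$serial,
    elety = at$name, chain = at$chain, insert = at$insert,
    o = rep(1, nrow(at)), b = rep(0, nrow(at)), elesy = at$element
  )
  invisible(file)
}
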
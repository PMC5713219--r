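# Geometric detection of interface hydrogen bonds, salt bridges and
# cation-pi contacts. Criteria are heavy-atom distance gates chosen within
# common structural-biology conventions (hydrogen-free structures are
# supported; when explicit hydrogens are present an additional D-H...A angle
# gate applies to hydrogen bonds). All thresholds are configurable.

# donor/acceptor heavy atoms by residue; "N"/"O"/"OXT" cover the backbone
HB_DONORS <- list(
  ARG = c("NE", "NH1", "NH2"), LYS = "NZ", HIS = c("ND1", "NE2"),
  TRP = "NE1", SER = "OG", THR = "OG1", TYR = "OH", ASN = "ND2",
  GLN = "NE2", CYS = "SG", backbone = "N"
)
HB_ACCEPTORS <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
  SER = "OG", THR = "OG1", TYR = "OH", HIS = c("ND1", "NE2"), MET = "SD",
  CYS = "SG", backbone = c("O", "OXT")
)
CATIONIC_ATOMS <- list(
  LYS = "NZ", ARG = c("NE", "NH1", "NH2"), HIS = c("ND1", "NE2")
)
ANIONIC_ATOMS <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), backbone = "OXT"
)
AROMATIC_RINGS <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2")
)
CATION_CENTERS <- list(ARG = "CZ", LYS = "NZ")

.atoms_matching <- function(at, roles) {
  hit <- logical(nrow(at))
  for (res in names(roles)) {
    if (res == "backbone") {
      hit <- hit | (at$name %in% roles[[res]] &
                      at$resname %in% STANDARD_AA)
    } else {
      hit <- hit | (at$resname == res & at$name %in% roles[[res]])
    }
  }
  which(hit)
}

.atom_id <- function(at, i) {
  data.frame(chain = at$chain[i], resno = at$resno[i],
             resname = at$resname[i], atom = at$name[i],
             stringsAsFactors = FALSE)
}

.pair_records <- function(kind, at, coords, ia, ib, max_dist, frame) {
  if (length(ia) == 0 || length(ib) == 0) return(.empty_records())
  d2 <- .cross_dist2(coords[ia, , drop = FALSE], coords[ib, , drop = FALSE])
  hits <- which(d2 <= max_dist^2, arr.ind = TRUE)
  if (nrow(hits) == 0) return(.empty_records())
  rows <- lapply(seq_len(nrow(hits)), function(k) {
    i <- ia[hits[k, 1]]; j <- ib[hits[k, 2]]
    cbind(kind = kind,
          stats::setNames(.atom_id(at, i),
                          c("chain_a", "resno_a", "resname_a", "atom_a")),
          stats::setNames(.atom_id(at, j),
                          c("chain_b", "resno_b", "resname_b", "atom_b")),
          distance = sqrt(d2[hits[k, 1], hits[k, 2]]), frame = frame)
  })
  do.call(rbind, rows)
}

.empty_records <- function() {
  data.frame(kind = character(0), chain_a = character(0),
             resno_a = integer(0), resname_a = character(0),
             atom_a = character(0), chain_b = character(0),
             resno_b = integer(0), resname_b = character(0),
             atom_b = character(0), distance = numeric(0),
             frame = integer(0), stringsAsFactors = FALSE)
}

# drop duplicate pairs (a-b vs b-a) and order by distance
.dedup_records <- function(rec) {
  if (nrow(rec) == 0) return(rec)
  key1 <- paste(rec$chain_a, rec$resno_a, rec$atom_a)
  key2 <- paste(rec$chain_b, rec$resno_b, rec$atom_b)
  lo <- pmin(key1, key2); hi <- pmax(key1, key2)
  rec <- rec[!duplicated(paste(rec$kind, lo, hi)), , drop = FALSE]
  rec <- rec[order(rec$distance), , drop = FALSE]
  rownames(rec) <- NULL
  rec
}

.check_chains <- function(structure, chain_pair) {
  present <- unique(structure$atoms$chain)
  missing <- setdiff(chain_pair, present)
  if (length(missing) > 0) {
    stop("chain(s) not present in structure: ",
         paste(missing, collapse = ", "))
  }
}

#' Detect interface hydrogen bonds
#'
#' Donor-acceptor heavy-atom pairs across the two chains (N/O/S donors with
#' implied hydrogens, N/O/S acceptors) within `max_dist` (boundary
#' inclusive). If an explicit hydrogen bound to the donor is present, the
#' D-H...A angle must additionally be at least `min_angle` degrees.
#'
#' @param structure an [md_structure()].
#' @param chain_pair length-2 character vector of chain ids.
#' @param max_dist donor-acceptor heavy-atom cutoff in Angstrom
#'   (default 3.9).
#' @param min_angle D-H...A angle gate in degrees, applied only when an
#'   explicit hydrogen is present (default 120).
#' @param frame frame index recorded on the output (default 1).
#' @return data.frame of interaction records (kind, the two atom
#'   identities, distance, frame), ordered by distance.
#' @export
find_hbonds <- function(structure, chain_pair, max_dist = 3.9,
                        min_angle = 120, frame = 1) {
  .check_chains(structure, chain_pair)
  at <- structure$atoms
  coords <- structure_coords(structure)
  rec <- .empty_records()
  for (swap in list(c(1, 2), c(2, 1))) {
    don <- intersect(.atoms_matching(at, HB_DONORS),
                     which(at$chain == chain_pair[swap[1]]))
    acc <- intersect(.atoms_matching(at, HB_ACCEPTORS),
                     which(at$chain == chain_pair[swap[2]]))
    rec <- rbind(rec, .pair_records("hbond", at, coords, don, acc,
                                    max_dist, frame))
  }
  rec <- .angle_gate(rec, at, coords, min_angle)
  .dedup_records(rec)
}

# apply the D-H...A gate where the donor has explicit hydrogens
.angle_gate <- function(rec, at, coords, min_angle) {
  if (nrow(rec) == 0) return(rec)
  keep <- rep(TRUE, nrow(rec))
  for (k in seq_len(nrow(rec))) {
    di <- which(at$chain == rec$chain_a[k] & at$resno == rec$resno_a[k] &
                  at$name == rec$atom_a[k])
    hyd <- which(at$chain == rec$chain_a[k] & at$resno == rec$resno_a[k] &
                   at$element == "H")
    if (length(hyd) == 0) next
    # hydrogens within covalent range of the donor heavy atom
    dh <- sqrt(.cross_dist2(coords[di, , drop = FALSE],
                            coords[hyd, , drop = FALSE]))
    hyd <- hyd[dh[1, ] <= 1.3]
    if (length(hyd) == 0) next
    ai <- which(at$chain == rec$chain_b[k] & at$resno == rec$resno_b[k] &
                  at$name == rec$atom_b[k])
    angles <- vapply(hyd, function(h) {
      v1 <- coords[di, ] - coords[h, ]
      v2 <- coords[ai, ] - coords[h, ]
      acos(pmin(pmax(sum(v1 * v2) /
                       (sqrt(sum(v1^2)) * sqrt(sum(v2^2))), -1), 1)) * 180 / pi
    }, numeric(1))
    keep[k] <- any(angles >= min_angle)
  }
  rec[keep, , drop = FALSE]
}

#' Detect interface salt bridges
#'
#' Pairs of cationic side-chain atoms (Lys NZ; Arg NE/NH1/NH2; His
#' ND1/NE2) and anionic atoms (Asp OD1/OD2; Glu OE1/OE2; C-terminal OXT)
#' across the two chains within `max_dist` (boundary inclusive).
#'
#' @inheritParams find_hbonds
#' @param max_dist N-O distance cutoff in Angstrom (default 4.0).
#' @return data.frame of interaction records.
#' @export
find_salt_bridges <- function(structure, chain_pair, max_dist = 4.0,
                              frame = 1) {
  .check_chains(structure, chain_pair)
  at <- structure$atoms
  coords <- structure_coords(structure)
  rec <- .empty_records()
  for (swap in list(c(1, 2), c(2, 1))) {
    cat_i <- intersect(.atoms_matching(at, CATIONIC_ATOMS),
                       which(at$chain == chain_pair[swap[1]]))
    ani_i <- intersect(.atoms_matching(at, ANIONIC_ATOMS),
                       which(at$chain == chain_pair[swap[2]]))
    rec <- rbind(rec, .pair_records("salt_bridge", at, coords, cat_i, ani_i,
                                    max_dist, frame))
  }
  .dedup_records(rec)
}

#' Detect interface cation-pi contacts
#'
#' A cationic group centre (Arg guanidinium CZ or Lys NZ) within `max_dist`
#' of an aromatic ring centroid (Phe/Tyr/Trp six-ring, His five-ring) on the
#' other chain, with the angle between the ring normal and the
#' centroid-to-cation vector at most `max_angle` degrees (i.e. the cation
#' sits over the ring face, not in its plane).
#'
#' @inheritParams find_hbonds
#' @param max_dist centroid-to-cation cutoff in Angstrom (default 6.0).
#' @param max_angle ring-normal angle gate in degrees (default 45).
#' @return data.frame of interaction records (`atom_b` is the ring residue,
#'   reported as its centroid with atom name `"RING"`).
#' @export
find_cation_pi <- function(structure, chain_pair, max_dist = 6.0,
                           max_angle = 45, frame = 1) {
  .check_chains(structure, chain_pair)
  at <- structure$atoms
  coords <- structure_coords(structure)
  rec <- .empty_records()
  for (swap in list(c(1, 2), c(2, 1))) {
    cat_i <- intersect(.atoms_matching(at, CATION_CENTERS),
                       which(at$chain == chain_pair[swap[1]]))
    rings <- .find_rings(at, chain_pair[swap[2]])
    for (ci in cat_i) {
      for (ring in rings) {
        centroid <- colMeans(coords[ring$idx, , drop = FALSE])
        v <- coords[ci, ] - centroid
        d <- sqrt(sum(v^2))
        if (d > max_dist) next
        normal <- .ring_normal(coords[ring$idx, , drop = FALSE])
        cosang <- abs(sum(v * normal)) / d
        ang <- acos(pmin(pmax(cosang, 0), 1)) * 180 / pi
        if (ang > max_angle) next
        row <- cbind(kind = "cation_pi",
                     stats::setNames(.atom_id(at, ci),
                                     c("chain_a", "resno_a", "resname_a",
                                       "atom_a")),
                     chain_b = ring$chain, resno_b = ring$resno,
                     resname_b = ring$resname, atom_b = "RING",
                     distance = d, frame = frame)
        rec <- rbind(rec, row)
      }
    }
  }
  .dedup_records(rec)
}

.find_rings <- function(at, chain) {
  out <- list()
  rows <- which(at$chain == chain & at$resname %in% names(AROMATIC_RINGS))
  if (length(rows) == 0) return(out)
  rid <- paste(at$resno[rows], at$insert[rows])
  for (r in unique(rid)) {
    rr <- rows[rid == r]
    resname <- at$resname[rr[1]]
    want <- AROMATIC_RINGS[[resname]]
    idx <- rr[match(want, at$name[rr])]
    if (anyNA(idx)) {
      warning("aromatic ring with missing atoms skipped: ", resname, " ",
              at$resno[rr[1]], " chain ", chain)
      next
    }
    out[[length(out) + 1]] <- list(idx = idx, chain = chain,
                                   resno = at$resno[rr[1]],
                                   resname = resname)
  }
  out
}

# unit normal of the best plane through the ring atoms
.ring_normal <- function(ring_coords) {
  c0 <- sweep(ring_coords, 2, colMeans(ring_coords))
  sv <- svd(c0)
  n <- sv$v[, 3]
  n / sqrt(sum(n^2))
}

#' Per-residue interaction census
#'
#' Counts, for every residue appearing in the records (on either side), its
#' hydrogen bonds, salt bridges and cation-pi contacts, sorted by total
#' count; the top rows identify the residues most engaged at the interface.
#'
#' @param records data.frame of interaction records from the `find_*`
#'   detectors (may be rbind-ed across kinds/frames).
#' @return data.frame with columns `residue`, `n_hbond`, `n_salt_bridge`,
#'   `n_cation_pi`, `total`, sorted by decreasing `total`.
#' @export
residue_interaction_census <- function(records) {
  empty <- data.frame(residue = character(0), n_hbond = integer(0),
                      n_salt_bridge = integer(0), n_cation_pi = integer(0),
                      total = integer(0), stringsAsFactors = FALSE)
  if (is.null(records) || nrow(records) == 0) return(empty)
  res_a <- paste0(records$chain_a, ":", records$resname_a, records$resno_a)
  res_b <- paste0(records$chain_b, ":", records$resname_b, records$resno_b)
  long <- data.frame(residue = c(res_a, res_b),
                     kind = rep(records$kind, 2), stringsAsFactors = FALSE)
  tab <- table(long$residue, factor(long$kind,
                                    levels = c("hbond", "salt_bridge",
                                               "cation_pi")))
  out <- data.frame(residue = rownames(tab),
                    n_hbond = as.integer(tab[, "hbond"]),
                    n_salt_bridge = as.integer(tab[, "salt_bridge"]),
                    n_cation_pi = as.integer(tab[, "cation_pi"]),
                    stringsAsFactors = FALSE)
  out$total <- out$n_hbond + out$n_salt_bridge + out$n_cation_pi
  out <- out[order(-out$total, out$residue), , drop = FALSE]
  rownames(out) <- NULL
  out
}
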
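# MM/GBSA end-state bookkeeping and the gas-phase/nonpolar primitives.
#
# The binding free energy is assembled per frame as
#   dG_binding = dG_gas + dG_solvation - TdS
#   dG_gas     = dE_vdW + dE_ele + dE_int
#   dG_solv    = dG_polar (GB, consumed from an input table) + dG_nonpolar
#   dG_nonpolar = gamma * SASA + b       (gamma = 0.00542 kcal/mol/A^2,
#                                         b = 0.92 kcal/mol)
# with every delta taken as complex - receptor - ligand. The entropy term
# -TdS is 0 by default (relative orderings only). The polar (GB) solvation
# term is never computed here: implementing a continuum-electrostatics
# solver is out of scope, so it is consumed from per-frame input tables.

COULOMB_CONST <- 332.0637  # kcal A / (mol e^2)

# Bondi van der Waals radii (Angstrom) by element
BONDI_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
                 P = 1.80, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98)

#' Gas-phase nonbonded energies of a parameterised system
#'
#' Plain pairwise sums with truncation at `cutoff` (no switching function):
#' `E_ele = sum 332.0637 q_i q_j / r_ij` and
#' `E_vdW = sum 4 eps_ij [(sigma_ij/r)^12 - (sigma_ij/r)^6]` with
#' Lorentz-Berthelot combining (`sigma_ij = (sigma_i + sigma_j)/2`,
#' `eps_ij = sqrt(eps_i eps_j)`).
#'
#' @param structure an [md_structure()].
#' @param parameters data.frame with columns `serial`, `charge` (e),
#'   `eps` (kcal/mol), `sigma` (Angstrom) covering every atom.
#' @param cutoff pair-distance cutoff in Angstrom (default 10).
#' @param exclusions optional data.frame/matrix of serial pairs (bonded
#'   exclusions) to skip.
#' @return list with `E_vdw` and `E_ele` in kcal/mol.
#' @export
nonbonded_energy <- function(structure, parameters, cutoff = 10.0,
                             exclusions = NULL) {
  if (cutoff <= 0) stop("cutoff must be positive")
  at <- structure$atoms
  m <- match(at$serial, parameters$serial)
  if (anyNA(m)) {
    stop("missing parameters for atom serial(s): ",
         paste(at$serial[is.na(m)], collapse = ", "))
  }
  q <- parameters$charge[m]
  eps <- parameters$eps[m]
  sig <- parameters$sigma[m]
  coords <- structure_coords(structure)
  n <- nrow(coords)
  excl <- matrix(FALSE, n, n)
  if (!is.null(exclusions)) {
    exclusions <- as.matrix(exclusions)
    for (r in seq_len(nrow(exclusions))) {
      i <- match(exclusions[r, 1], at$serial)
      j <- match(exclusions[r, 2], at$serial)
      excl[i, j] <- excl[j, i] <- TRUE
    }
  }
  e_vdw <- 0; e_ele <- 0
  for (i in seq_len(max(n - 1, 0))) {
    for (j in (i + 1):n) {
      if (excl[i, j]) next
      r <- sqrt(sum((coords[i, ] - coords[j, ])^2))
      if (r > cutoff) next
      e_ele <- e_ele + COULOMB_CONST * q[i] * q[j] / r
      sij <- (sig[i] + sig[j]) / 2
      eij <- sqrt(eps[i] * eps[j])
      sr6 <- (sij / r)^6
      e_vdw <- e_vdw + 4 * eij * (sr6^2 - sr6)
    }
  }
  list(E_vdw = e_vdw, E_ele = e_ele)
}

# near-uniform points on the unit sphere (golden-spiral construction);
# deterministic for a given count
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' For each atom, test points on a sphere of radius `r_atom + probe` are
#' flagged accessible when outside every neighbour's expanded sphere; the
#' accessible fraction times the expanded-sphere area gives the atom's SASA.
#'
#' @param structure an [md_structure()].
#' @param probe probe radius in Angstrom (default 1.4).
#' @param n_points test points per atom (default 960).
#' @param radii optional radii override: a named vector by element symbol
#'   (merged over the built-in Bondi set), or a numeric vector with one
#'   radius per atom.
#' @return list with `atom_area` (per-atom, Angstrom^2) and `total`.
#' @export
sasa <- function(structure, probe = 1.4, n_points = 960, radii = NULL) {
  if (probe < 0) stop("probe radius must be nonnegative")
  at <- structure$atoms
  n <- nrow(at)
  if (!is.null(radii) && is.null(names(radii))) {
    if (length(radii) != n) stop("per-atom radii must match atom count")
    r_atom <- as.numeric(radii)
  } else {
    tab <- BONDI_RADII
    if (!is.null(radii)) tab[toupper(names(radii))] <- radii
    r_atom <- tab[toupper(at$element)]
    if (anyNA(r_atom)) {
      stop("no radius for element(s): ",
           paste(unique(at$element[is.na(r_atom)]), collapse = ", "))
    }
  }
  coords <- structure_coords(structure)
  rext <- r_atom + probe
  pts <- .sphere_points(n_points)
  area <- numeric(n)
  for (i in seq_len(n)) {
    sphere <- sweep(pts * rext[i], 2, coords[i, ], FUN = "+")
    free <- rep(TRUE, n_points)
    for (j in seq_len(n)) {
      if (j == i) next
      dij2 <- sum((coords[i, ] - coords[j, ])^2)
      if (dij2 >= (rext[i] + rext[j])^2) next
      d2 <- rowSums(sweep(sphere, 2, coords[j, ])^2)
      free <- free & d2 > rext[j]^2
      if (!any(free)) break
    }
    area[i] <- mean(free) * 4 * pi * rext[i]^2
  }
  list(atom_area = area, total = sum(area))
}

#' Nonpolar solvation free energy from a surface area
#'
#' `dG_nonpolar = gamma * SASA + b`.
#'
#' @param sasa_total surface area in Angstrom^2 (>= 0).
#' @param gamma surface-tension coefficient, kcal/mol/A^2
#'   (default 0.00542).
#' @param b offset, kcal/mol (default 0.92).
#' @return kcal/mol.
#' @export
nonpolar_solvation <- function(sasa_total, gamma = 0.00542, b = 0.92) {
  if (any(sasa_total < 0)) stop("SASA must be nonnegative")
  gamma * sasa_total + b
}

#' Per-frame energy components for one role of an end-state calculation
#'
#' @param role `"complex"`, `"receptor"` or `"ligand"`.
#' @param table data.frame with per-frame columns `E_vdw`, `E_ele`,
#'   `G_polar`, `G_nonpolar` and optionally `E_int` (default 0) and `frame`.
#' @return an `energy_components` object.
#' @export
energy_components <- function(role = c("complex", "receptor", "ligand"),
                              table) {
  role <- match.arg(role)
  table <- as.data.frame(table)
  needed <- c("E_vdw", "E_ele", "G_polar", "G_nonpolar")
  missing <- setdiff(needed, names(table))
  if (length(missing) > 0) {
    stop("component table is missing: ", paste(missing, collapse = ", "))
  }
  if (!("E_int" %in% names(table))) table$E_int <- 0
  if (!("frame" %in% names(table))) table$frame <- seq_len(nrow(table))
  num <- table[, c("E_vdw", "E_ele", "E_int", "G_polar", "G_nonpolar")]
  if (!all(vapply(num, function(col) all(is.finite(col)), logical(1)))) {
    stop("non-finite energy component values")
  }
  structure(list(role = role, table = table), class = "energy_components")
}

#' Read per-frame energy components from a CSV file
#'
#' Expects columns `frame`, `role`, `E_vdw`, `E_ele`, `E_int`, `G_polar`,
#' `G_nonpolar`; returns one [energy_components()] per role.
#'
#' @param file CSV path.
#' @return named list with elements `complex`, `receptor`, `ligand` (those
#'   present in the file).
#' @export
read_energy_components <- function(file) {
  tab <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (!("role" %in% names(tab))) stop("CSV needs a 'role' column")
  out <- list()
  for (role in intersect(c("complex", "receptor", "ligand"),
                         unique(tab$role))) {
    out[[role]] <- energy_components(role, tab[tab$role == role,
                                               setdiff(names(tab), "role")])
  }
  out
}

#' MM/GBSA binding-energy summary ledger
#'
#' Per frame, every term is differenced as complex - receptor - ligand;
#' derived terms are `dG_gas = dE_vdw + dE_ele + dE_int`,
#' `dG_solvation = dG_gb + dG_surf` and
#' `dG_binding = dG_gas + dG_solvation - TdS`. Means and population SDs are
#' taken over frames.
#'
#' @param complex,receptor,ligand [energy_components()] objects with equal
#'   frame counts.
#' @param entropy_term the -TdS value in kcal/mol (default 0, i.e. the
#'   entropy contribution is omitted and only relative orderings of
#'   binding energies are meaningful).
#' @return a `binding_summary`: list with `deltas` (per-frame data.frame)
#'   and `summary` (data.frame `term`, `mean`, `sd`).
#' @export
binding_summary <- function(complex, receptor, ligand, entropy_term = 0) {
  roles <- list(complex = complex, receptor = receptor, ligand = ligand)
  for (nm in names(roles)) {
    stopifnot(inherits(roles[[nm]], "energy_components"))
  }
  fc <- vapply(roles, function(r) nrow(r$table), integer(1))
  if (length(unique(fc)) != 1) {
    stop("frame-count mismatch across roles: ",
         paste(fc, collapse = ", "))
  }
  comp <- c(E_vdw = "dE_vdw", E_ele = "dE_ele", E_int = "dE_int",
            G_polar = "dG_gb", G_nonpolar = "dG_surf")
  deltas <- data.frame(frame = roles$complex$table$frame)
  for (k in names(comp)) {
    deltas[[comp[k]]] <- roles$complex$table[[k]] -
      roles$receptor$table[[k]] - roles$ligand$table[[k]]
  }
  deltas$dG_gas <- deltas$dE_vdw + deltas$dE_ele + deltas$dE_int
  deltas$dG_solvation <- deltas$dG_gb + deltas$dG_surf
  deltas$dG_binding <- deltas$dG_gas + deltas$dG_solvation - entropy_term
  terms <- c("dE_vdw", "dE_ele", "dE_int", "dG_gb", "dG_surf",
             "dG_gas", "dG_solvation", "dG_binding")
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  summary <- data.frame(
    term = terms,
    mean = vapply(terms, function(t) mean(deltas[[t]]), numeric(1)),
    sd = vapply(terms, function(t) pop_sd(deltas[[t]]), numeric(1)),
    stringsAsFactors = FALSE
  )
  rownames(summary) <- NULL
  structure(list(deltas = deltas, summary = summary,
                 entropy_term = entropy_term),
            class = "binding_summary")
}

#' @export
print.binding_summary <- function(x, ...) {
  cat("MM/GBSA binding summary (kcal/mol; population SD over",
      nrow(x$deltas), "frame(s)):\n")
  s <- x$summary
  for (r in seq_len(nrow(s))) {
    cat(sprintf("  %-12s %9.2f (%.2f)\n", s$term[r], s$mean[r], s$sd[r]))
  }
  if (x$entropy_term != 0) cat("  -TdS        ", x$entropy_term, "\n")
  invisible(x)
}

#' Convenience: binding summary from already-differenced component values
#'
#' Wraps per-frame delta components (for example the printed component rows
#' of a published end-state table) as a complex-only [binding_summary()]
#' with zero receptor and ligand, so the derived totals are assembled by the
#' same ledger arithmetic.
#'
#' @param E_vdw,E_ele,G_polar,G_nonpolar,E_int per-frame delta component
#'   vectors (scalars are fine for single-snapshot ledgers).
#' @param entropy_term -TdS (default 0).
#' @return a `binding_summary`.
#' @export
delta_binding_summary <- function(E_vdw, E_ele, G_polar, G_nonpolar,
                                  E_int = 0, entropy_term = 0) {
  f <- max(lengths(list(E_vdw, E_ele, G_polar, G_nonpolar, E_int)))
  tab <- data.frame(E_vdw = rep(E_vdw, length.out = f),
                    E_ele = rep(E_ele, length.out = f),
                    E_int = rep(E_int, length.out = f),
                    G_polar = rep(G_polar, length.out = f),
                    G_nonpolar = rep(G_nonpolar, length.out = f))
  zero <- tab; zero[] <- 0
  binding_summary(energy_components("complex", tab),
                  energy_components("receptor", zero),
                  energy_components("ligand", zero),
                  entropy_term = entropy_term)
}

#' Term-by-term comparison of two binding summaries
#'
#' @param summary_a,summary_b `binding_summary` objects (for example wild
#'   type and mutant); the difference column is `b - a`.
#' @return data.frame `term`, `mean_a`, `sd_a`, `mean_b`, `sd_b`,
#'   `difference`.
#' @export
binding_comparison <- function(summary_a, summary_b) {
  a <- summary_a$summary; b <- summary_b$summary
  stopifnot(identical(a$term, b$term))
  data.frame(term = a$term, mean_a = a$mean, sd_a = a$sd,
             mean_b = b$mean, sd_b = b$sd,
             difference = b$mean - a$mean, stringsAsFactors = FALSE)
}

#' Per-residue free-energy decomposition difference table
#'
#' Differences per residue are `G_mut - G_wt`; residues whose contribution
#' to the binding free energy rises by strictly more than `threshold`
#' kcal/mol in the mutant are flagged. Residues present in only one system
#' are reported with an `NA` difference and never flagged.
#'
#' @param wt,mut data.frames with columns `residue`, `mean` and optionally
#'   `sd`.
#' @param threshold flag threshold in kcal/mol, strict inequality
#'   (default 0.3).
#' @return data.frame `residue`, `G_wt`, `sd_wt`, `G_mut`, `sd_mut`,
#'   `difference`, `flagged`.
#' @export
residue_decomposition <- function(wt, mut, threshold = 0.3) {
  wt <- as.data.frame(wt); mut <- as.data.frame(mut)
  if (!("sd" %in% names(wt))) wt$sd <- NA_real_
  if (!("sd" %in% names(mut))) mut$sd <- NA_real_
  residues <- union(wt$residue, mut$residue)
  iw <- match(residues, wt$residue)
  im <- match(residues, mut$residue)
  out <- data.frame(
    residue = residues,
    G_wt = wt$mean[iw], sd_wt = wt$sd[iw],
    G_mut = mut$mean[im], sd_mut = mut$sd[im],
    stringsAsFactors = FALSE
  )
  out$difference <- out$G_mut - out$G_wt
  out$flagged <- !is.na(out$difference) & out$difference > threshold
  out
}
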
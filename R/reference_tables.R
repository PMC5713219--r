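# Shipped reference tables for the H-Ras-NS1-GDP complex (wild type vs
# R135K): published end-state free-energy component means, per-residue
# decomposition means, interface contact geometry, and allosteric-path
# statistics. These drive the worked wild-type-versus-mutant comparison and
# the ledger worked examples; they are summary-level inputs, not
# trajectories.

.extdata <- function(name) {
  f <- system.file("extdata", name, package = "allodyn")
  if (f == "") stop("missing extdata file: ", name)
  f
}

#' Reference MM/GBSA component table (H-Ras-NS1-GDP, WT vs R135K)
#'
#' Mean and SD (kcal/mol) of the differenced end-state components
#' (`E_vdw`, `E_ele`, `G_polar` = GB term, `G_nonpolar` = surface term) and
#' of the assembled totals (`dG_gas`, `dG_binding`) for the wild-type and
#' R135K systems.
#'
#' @return data.frame with columns `system`, `term`, `mean`, `sd`.
#' @export
hras_ns1_energy_table <- function() {
  utils::read.csv(.extdata("hras_ns1_gbsa_components.csv"),
                  stringsAsFactors = FALSE)
}

#' Reference per-residue decomposition table (H-Ras-NS1-GDP, WT vs R135K)
#'
#' Per-residue binding free-energy contributions (mean, SD; kcal/mol) for
#' the residues whose contribution rises by more than 0.3 kcal/mol on
#' R135K mutation.
#'
#' @return data.frame with columns `group`, `residue`, `mean_wt`, `sd_wt`,
#'   `mean_r135k`, `sd_r135k`.
#' @export
hras_ns1_residue_table <- function() {
  utils::read.csv(.extdata("hras_ns1_residue_decomposition.csv"),
                  stringsAsFactors = FALSE)
}

#' Reference interface-contact geometry (NS1 side vs H-Ras R135/K135)
#'
#' Hydrogen bonds and salt bridges involving residue 135 of H-Ras, with the
#' participating atoms and their distances; side `a` is the NS1 monobody,
#' side `b` is H-Ras.
#'
#' @return data.frame with columns `system`, `id`, `kind`, `resname_a`,
#'   `resno_a`, `atom_a`, `resname_b`, `resno_b`, `atom_b`, `distance`.
#' @export
hras_ns1_interface_table <- function() {
  utils::read.csv(.extdata("hras_ns1_interface_contacts.csv"),
                  stringsAsFactors = FALSE)
}

#' Reference allosteric-path statistics (H-Ras, WT vs R135K)
#'
#' Optimal path length (scaled integer units), residues on the optimal
#' path, and suboptimal-path counts between residue 135 and the
#' binding-relevant residues, per system.
#'
#' @return data.frame with one row per residue pair.
#' @export
hras_ns1_path_table <- function() {
  utils::read.csv(.extdata("hras_ns1_path_table.csv"),
                  stringsAsFactors = FALSE)
}
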
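# Synthetic trajectories, planted graphs, interface geometries and toy
# charged/LJ systems with analytically known ground truth. These emulate the
# statistical structure of an MD ensemble (Gaussian residue fluctuations with
# a planted inter-residue correlation matrix) without any force-field physics,
# so every downstream estimator can be checked against what was planted.

#' Build an idealised C-alpha chain
#'
#' @param n_res number of residues (>= 2).
#' @param geometry `"line"` (3.8 A consecutive spacing along x) or `"helix"`
#'   (ideal alpha-helix C-alpha trace: rise 1.5 A/residue, 100 degrees twist,
#'   radius 2.3 A).
#' @param chain chain identifier.
#' @return an [md_structure()] with one `CA` atom per residue.
#' @export
make_chain <- function(n_res, geometry = c("line", "helix"), chain = "A") {
  geometry <- match.arg(geometry)
  if (n_res < 2) stop("n_res must be at least 2")
  i <- seq_len(n_res) - 1
  if (geometry == "line") {
    xyz <- cbind(3.8 * i, 0, 0)
  } else {
    theta <- i * 100 * pi / 180
    xyz <- cbind(2.3 * cos(theta), 2.3 * sin(theta), 1.5 * i)
  }
  md_structure(data.frame(
    serial = seq_len(n_res), name = "CA", element = "C",
    resno = seq_len(n_res), resname = "ALA", chain = chain, insert = "",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], stringsAsFactors = FALSE
  ), title = paste0("synthetic ", geometry, " chain"))
}

#' Specify a planted-fluctuation trajectory model
#'
#' Frames are drawn as `ref_i + amplitude * eta_i(t) * direction_i` with
#' `eta(t)` i.i.d. standard normal vectors whose correlation matrix is
#' `target_corr`. With the default common displacement direction the expected
#' dynamic cross-correlation matrix equals `target_corr` exactly, making
#' parameter recovery analytic.
#'
#' @param reference an [md_structure()] giving the mean positions (one
#'   fluctuating site per atom).
#' @param target_corr N x N symmetric positive-semidefinite correlation
#'   matrix (unit diagonal), N = number of atoms.
#' @param n_frames number of frames to draw.
#' @param seed integer seed; same seed gives a bit-identical trajectory.
#' @param amplitude fluctuation scale in Angstrom (> 0).
#' @param directions `NULL` for a single common unit direction (+x), or an
#'   N x 3 matrix of per-site unit displacement directions.
#' @return an object of class `planted_model`.
#' @export
planted_model <- function(reference, target_corr, n_frames, seed,
                          amplitude = 1.0, directions = NULL) {
  stopifnot(inherits(reference, "md_structure"))
  n <- n_atoms(reference)
  target_corr <- as.matrix(target_corr)
  if (!all(dim(target_corr) == c(n, n))) {
    stop("target_corr must be ", n, " x ", n)
  }
  if (max(abs(target_corr - t(target_corr))) > 1e-8) {
    stop("target_corr must be symmetric")
  }
  if (max(abs(diag(target_corr) - 1)) > 1e-8) {
    stop("target_corr must have unit diagonal")
  }
  if (amplitude <= 0) stop("amplitude must be positive")
  if (!is.null(directions)) {
    directions <- as.matrix(directions)
    stopifnot(all(dim(directions) == c(n, 3)))
    norms <- sqrt(rowSums(directions^2))
    directions <- directions / norms
  }
  structure(list(reference = reference, target_corr = target_corr,
                 n_frames = as.integer(n_frames), seed = as.integer(seed),
                 amplitude = amplitude, directions = directions),
            class = "planted_model")
}

# symmetric eigen square root; small negative eigenvalues are clipped,
# genuinely indefinite matrices are rejected
.corr_sqrt <- function(m, tol = 1e-10) {
  ev <- eigen(m, symmetric = TRUE)
  if (min(ev$values) < -tol * max(1, abs(ev$values[1]))) {
    stop("target correlation matrix is not positive semidefinite ",
         "(min eigenvalue ", signif(min(ev$values), 3), ")")
  }
  vals <- pmax(ev$values, 0)
  ev$vectors %*% (sqrt(vals) * t(ev$vectors))
}

#' Draw a trajectory from a planted-fluctuation model
#'
#' @param model a [planted_model()].
#' @return an [md_trajectory()] with `model$n_frames` frames.
#' @export
sample_correlated_trajectory <- function(model) {
  stopifnot(inherits(model, "planted_model"))
  n <- n_atoms(model$reference)
  l <- .corr_sqrt(model$target_corr)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(model$seed)
  z <- matrix(stats::rnorm(model$n_frames * n), model$n_frames, n)
  eta <- z %*% l  # rows now have correlation target_corr
  dirs <- if (is.null(model$directions)) {
    matrix(rep(c(1, 0, 0), n), n, 3, byrow = TRUE)
  } else {
    model$directions
  }
  ref <- structure_coords(model$reference)
  xyz <- matrix(0, model$n_frames, 3 * n)
  for (k in 1:3) {
    cols <- seq(k, 3 * n, by = 3)
    xyz[, cols] <- matrix(ref[, k], model$n_frames, n, byrow = TRUE) +
      model$amplitude * eta * matrix(dirs[, k], model$n_frames, n, byrow = TRUE)
  }
  md_trajectory(model$reference, xyz)
}

#' Plant a correlation matrix and contact map realising a given graph
#'
#' Builds the inputs from which [build_graph()] reconstructs exactly the
#' requested residue network: the correlation matrix carries the requested
#' `|X|` on the listed pairs (0 elsewhere off-diagonal) and the contact map
#' admits exactly those pairs.
#'
#' @param n_nodes number of residues/nodes.
#' @param edges data.frame (or matrix) with columns `i`, `j`, `x`: node pairs
#'   (1-based) and their correlation magnitude in (0, 1].
#' @return list with `correlation` (N x N), `contacts` (N x N logical) and
#'   `labels`.
#' @export
plant_path_graph <- function(n_nodes, edges) {
  edges <- as.data.frame(edges)
  names(edges)[1:3] <- c("i", "j", "x")
  if (any(edges$x <= 0 | edges$x > 1)) {
    stop("edge |X| values must lie in (0, 1]")
  }
  if (any(edges$i == edges$j)) stop("self-loops are not allowed")
  corr <- diag(n_nodes)
  contacts <- matrix(FALSE, n_nodes, n_nodes)
  for (r in seq_len(nrow(edges))) {
    i <- edges$i[r]; j <- edges$j[r]
    corr[i, j] <- corr[j, i] <- edges$x[r]
    contacts[i, j] <- contacts[j, i] <- TRUE
  }
  g <- igraph::graph_from_adjacency_matrix(contacts, mode = "undirected")
  if (!igraph::is_connected(g)) stop("planted edges must form a connected graph")
  labels <- paste0("N", seq_len(n_nodes))
  dimnames(corr) <- list(labels, labels)
  dimnames(contacts) <- list(labels, labels)
  list(correlation = corr, contacts = contacts, labels = labels)
}

# minimal side-chain templates used by the interface fixtures; the key atom
# is placed at the residue origin, a CA 2.4 A away keeps geometry sane
.fixture_residue <- function(resname, atom, origin, chain, resno, serial0) {
  ca <- origin + c(-2.4, 0, 0)
  if (chain == "B") ca <- origin + c(2.4, 0, 0)
  data.frame(
    serial = serial0 + 0:1, name = c("CA", atom), element = c("C",
      substr(gsub("^[0-9]*", "", atom), 1, 1)),
    resno = resno, resname = resname, chain = chain, insert = "",
    x = c(ca[1], origin[1]), y = c(ca[2], origin[2]), z = c(ca[3], origin[3]),
    stringsAsFactors = FALSE
  )
}

#' Build a two-chain interaction-geometry fixture
#'
#' Places a donor/acceptor pair (hydrogen bond), a charged pair (salt
#' bridge), or a cation above an aromatic six-ring (cation-pi) at exactly the
#' requested distance, on two different chains (A and B).
#'
#' @param kind `"hbond"`, `"salt_bridge"` or `"cation_pi"`.
#' @param distance key-atom (or centroid-to-cation) distance in Angstrom.
#' @param group_a,group_b optional lists `list(resname=, atom=, resno=)`
#'   overriding the default participating groups. For `cation_pi`, group_a is
#'   always the aromatic ring (TYR) and only group_b (the cation) is
#'   configurable.
#' @param angle for `cation_pi`: angle in degrees between the ring normal and
#'   the centroid-to-cation vector (default 0 = directly above the ring).
#' @return an [md_structure()].
#' @export
make_interaction_fixture <- function(kind = c("hbond", "salt_bridge",
                                              "cation_pi"),
                                     distance,
                                     group_a = NULL, group_b = NULL,
                                     angle = 0) {
  kind <- match.arg(kind)
  if (distance <= 0) stop("distance must be positive")
  defaults <- switch(kind,
    hbond = list(a = list(resname = "GLU", atom = "OE1", resno = 49),
                 b = list(resname = "ARG", atom = "NE", resno = 135)),
    salt_bridge = list(a = list(resname = "GLU", atom = "OE2", resno = 49),
                       b = list(resname = "LYS", atom = "NZ", resno = 135)),
    cation_pi = list(a = list(resname = "TYR", atom = NULL, resno = 31),
                     b = list(resname = "ARG", atom = "CZ", resno = 135))
  )
  ga <- utils::modifyList(defaults$a, if (is.null(group_a)) list() else group_a)
  gb <- utils::modifyList(defaults$b, if (is.null(group_b)) list() else group_b)

  if (kind != "cation_pi") {
    a <- .fixture_residue(ga$resname, ga$atom, c(0, 0, 0), "A", ga$resno, 1)
    b <- .fixture_residue(gb$resname, gb$atom, c(distance, 0, 0), "B",
                          gb$resno, 3)
    return(md_structure(rbind(a, b), title = paste("synthetic", kind)))
  }
  # aromatic 6-ring of TYR in the xy-plane, centroid at origin, normal +z
  ring_names <- c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")
  ring_order <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")  # hexagon order
  th <- (0:5) * 60 * pi / 180
  ring <- data.frame(
    serial = 1:6, name = ring_order, element = "C",
    resno = ga$resno, resname = "TYR", chain = "A", insert = "",
    x = 1.39 * cos(th), y = 1.39 * sin(th), z = 0, stringsAsFactors = FALSE
  )
  ring <- ring[match(ring_names, ring$name), ]
  ring$serial <- 1:6
  arad <- angle * pi / 180
  cat_pos <- distance * c(sin(arad), 0, cos(arad))
  b <- .fixture_residue(gb$resname, gb$atom, cat_pos, "B", gb$resno, 7)
  md_structure(rbind(ring, b), title = "synthetic cation-pi")
}

#' Build a two-particle charged/Lennard-Jones toy system
#'
#' Two particles on the x-axis at separation `r`, with charges and LJ
#' parameters supplied as a table suitable for [nonbonded_energy()].
#'
#' @param q1,q2 charges (elementary charge units).
#' @param eps LJ well depth, kcal/mol (shared by both particles).
#' @param sigma LJ sigma, Angstrom (shared).
#' @param r separation in Angstrom (> 0).
#' @return list with `structure` (an [md_structure()]) and `parameters`
#'   (data.frame `serial`, `charge`, `eps`, `sigma`).
#' @export
make_two_particle_system <- function(q1, q2, eps, sigma, r) {
  if (r <= 0) stop("separation r must be positive")
  s <- md_structure(data.frame(
    serial = 1:2, name = c("P1", "P2"), element = "X",
    resno = 1:2, resname = "LJP", chain = "A", insert = "",
    x = c(0, r), y = 0, z = 0, stringsAsFactors = FALSE
  ), title = "two-particle toy system")
  params <- data.frame(serial = 1:2, charge = c(q1, q2),
                       eps = eps, sigma = sigma)
  list(structure = s, parameters = params)
}
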
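# Correlation-weighted residue interaction network and path analysis.
#
# Each residue (its C-alpha) is a node; an edge joins residues that are in
# contact and dynamically coupled, with length d_ij = -ln|X_ij| where X_ij is
# the DCCM entry. Lengths are scaled to integers (x100 by default) as in the
# established dynamical-network convention, so a suboptimal-path offset of 20
# means 0.2 in raw -ln units. Strong coupling (|X| near 1) gives short edges:
# short optimal paths, few involved residues and many suboptimal paths all
# indicate a stronger allosteric relationship.

#' Residue-residue contact map over a trajectory
#'
#' A pair is in contact when its distance is within `cutoff` in at least an
#' `occupancy` fraction of the window's frames. In `"heavy"` mode the
#' minimum distance over all non-hydrogen atoms of the two residues is used
#' (cutoff default 4.5 A); `"calpha"` mode uses C-alpha distance with an
#' 8.0 A default. Sequence neighbours within `exclude_neighbors` positions
#' on the same chain are excluded.
#'
#' @param traj an [md_trajectory()].
#' @param selection integer atom indices defining the residues (one atom per
#'   residue in `"calpha"` mode; in `"heavy"` mode all atoms of each listed
#'   residue are used). Default: C-alpha selection of the topology.
#' @param cutoff distance cutoff in Angstrom; `NULL` picks the mode default.
#' @param occupancy required fraction of frames in (0, 1] (default 0.75).
#' @param mode `"heavy"` or `"calpha"`.
#' @param exclude_neighbors exclude |i-j| <= this many sequence positions on
#'   the same chain (default 2).
#' @param window frame window.
#' @return a `contact_map` list: `map` (N x N logical, symmetric, FALSE
#'   diagonal), `labels`, `cutoff`, `occupancy`.
#' @export
contact_map <- function(traj, selection = NULL, cutoff = NULL,
                        occupancy = 0.75, mode = c("heavy", "calpha"),
                        exclude_neighbors = 2, window = NULL) {
  mode <- match.arg(mode)
  if (is.null(cutoff)) cutoff <- if (mode == "heavy") 4.5 else 8.0
  if (cutoff <= 0) stop("cutoff must be positive")
  if (occupancy <= 0 || occupancy > 1) stop("occupancy must be in (0, 1]")
  if (is.null(selection)) selection <- select_calpha(traj$topology)
  selection <- check_selection(traj, selection)
  window <- .resolve_window(traj, window)
  at <- traj$topology$atoms
  rid <- paste(at$chain[selection], at$resno[selection],
               at$insert[selection])
  ures <- unique(rid)
  n <- length(ures)
  # atom groups per residue: representative atoms only, or all heavy atoms
  groups <- if (mode == "calpha") {
    lapply(ures, function(r) selection[rid == r])
  } else {
    lapply(ures, function(r) {
      ch <- at$chain[selection[rid == r][1]]
      rn <- at$resno[selection[rid == r][1]]
      ins <- at$insert[selection[rid == r][1]]
      idx <- which(at$chain == ch & at$resno == rn & at$insert == ins &
                     at$element != "H")
      idx
    })
  }
  hits <- matrix(0L, n, n)
  for (f in window) {
    m <- frame_coords(traj, f)
    for (i in seq_len(n - 1)) {
      gi <- m[groups[[i]], , drop = FALSE]
      for (j in (i + 1):n) {
        gj <- m[groups[[j]], , drop = FALSE]
        d2 <- min(.cross_dist2(gi, gj))
        if (d2 <= cutoff^2) hits[i, j] <- hits[i, j] + 1L
      }
    }
  }
  map <- (hits + t(hits)) >= occupancy * length(window)
  diag(map) <- FALSE
  # neighbour exclusion within a chain
  first <- vapply(ures, function(r) selection[rid == r][1], integer(1))
  ch <- at$chain[first]; rn <- at$resno[first]
  for (i in seq_len(n)) {
    near <- ch == ch[i] & abs(rn - rn[i]) <= exclude_neighbors
    map[i, near] <- FALSE
    map[near, i] <- FALSE
  }
  labels <- residue_labels(traj$topology, first)
  dimnames(map) <- list(labels, labels)
  structure(list(map = map, labels = labels, cutoff = cutoff,
                 occupancy = occupancy, mode = mode),
            class = "contact_map")
}

.cross_dist2 <- function(a, b) {
  outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
}

#' Build the correlation-weighted residue graph
#'
#' An edge joins each contact pair with `|X| > 0`; its raw length is
#' `-ln|X|` and its integer length `round(scale * raw)` (half away from
#' zero). Contact pairs with `|X| = 0` get no edge (infinite distance) and a
#' warning.
#'
#' @param dccm N x N correlation matrix (a [dccm()] result or plain matrix).
#' @param contacts a [contact_map()], or an N x N logical matrix admitting
#'   edges (for example from [plant_path_graph()]).
#' @param scale integer length scale (default 100).
#' @return a `residue_graph`: an igraph with vertex attribute `name` and
#'   edge attributes `abs_x`, `raw_weight`, `int_length`.
#' @export
build_graph <- function(dccm, contacts, scale = 100) {
  if (inherits(contacts, "contact_map")) contacts <- contacts$map
  contacts <- as.matrix(contacts)
  x <- unclass(as.matrix(dccm))
  if (!all(dim(x) == dim(contacts))) {
    stop("dccm (", nrow(x), ") and contacts (", nrow(contacts),
         ") dimensions differ")
  }
  n <- nrow(x)
  labels <- rownames(x)
  if (is.null(labels)) labels <- paste0("N", seq_len(n))
  pairs <- which(upper.tri(contacts) & contacts, arr.ind = TRUE)
  if (nrow(pairs) > 0) {
    ax <- abs(x[pairs])
    dropped <- ax == 0
    if (any(dropped)) {
      warning(sum(dropped), " contact pair(s) with |X| = 0 dropped ",
              "(infinite network distance)")
    }
    pairs <- pairs[!dropped, , drop = FALSE]
    ax <- ax[!dropped]
  } else {
    ax <- numeric(0)
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = labels)
  if (nrow(pairs) > 0) {
    raw <- -log(ax)
    g <- igraph::add_edges(g, t(pairs))
    g <- igraph::set_edge_attr(g, "abs_x", value = ax)
    g <- igraph::set_edge_attr(g, "raw_weight", value = raw)
    g <- igraph::set_edge_attr(g, "int_length",
                               value = .round_half_away(scale * raw))
  }
  class(g) <- c("residue_graph", class(g))
  attr(g, "scale") <- scale
  g
}

.round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

.node_index <- function(graph, node) {
  names <- igraph::V(graph)$name
  if (is.character(node)) {
    i <- match(node, names)
    if (is.na(i)) stop("node not in graph: ", node)
    i
  } else {
    if (node < 1 || node > length(names)) stop("node index out of range")
    as.integer(node)
  }
}

#' Optimal (shortest) path between two residues
#'
#' Dijkstra on integer edge lengths. Ties are broken deterministically:
#' fewest nodes first, then lexicographic node order.
#'
#' @param graph a [build_graph()] result.
#' @param source,sink node labels or indices.
#' @return a `path_result` list: `source`, `sink`, `found`, `path`
#'   (node labels), `length` (integer scaled units), `n_residues`,
#'   `suboptimal_count` (NA until [suboptimal_paths()] fills it).
#' @export
optimal_path <- function(graph, source, sink) {
  si <- .node_index(graph, source); ti <- .node_index(graph, sink)
  names <- igraph::V(graph)$name
  res <- list(source = names[si], sink = names[ti], found = FALSE,
              path = character(0), length = NA_integer_,
              n_residues = NA_integer_, suboptimal_count = NA_integer_,
              node_frequency = NULL, truncated = FALSE)
  class(res) <- "path_result"
  if (si == ti) {
    res$found <- TRUE; res$path <- names[si]; res$length <- 0L
    res$n_residues <- 1L
    return(res)
  }
  w <- igraph::E(graph)$int_length
  d <- igraph::distances(graph, v = si, to = ti, weights = w)[1, 1]
  if (!is.finite(d)) return(res)  # explicit no-path result
  all_sp <- igraph::all_shortest_paths(graph, from = si, to = ti,
                                       weights = w)$vpaths
  paths <- lapply(all_sp, function(p) names[as.integer(p)])
  best <- paths[[.pick_path(paths)]]
  res$found <- TRUE
  res$path <- best
  res$length <- as.integer(round(d))
  res$n_residues <- length(best)
  res
}

# deterministic choice among candidate paths: fewest nodes, then
# lexicographic on the node-label sequence
.pick_path <- function(paths) {
  lens <- lengths(paths)
  cand <- which(lens == min(lens))
  if (length(cand) == 1) return(cand)
  keys <- vapply(paths[cand],
                 function(p) paste(p, collapse = "\r"), character(1))
  cand[order(keys)[1]]
}

#' Enumerate suboptimal paths within an offset of the optimum
#'
#' All simple paths whose total integer length is at most
#' `optimal + offset` are enumerated by depth-first search with admissible
#' pruning (a reverse-Dijkstra lower bound on the remaining distance).
#' `suboptimal_count` excludes the optimal path itself; `node_frequency`
#' counts node occurrences over the full enumerated set.
#'
#' @param graph a [build_graph()] result.
#' @param source,sink node labels or indices.
#' @param offset allowed excess over the optimal integer length
#'   (default 20, i.e. 0.2 in raw -ln units at the default scale).
#' @param max_paths safety cap; if reached, the result is flagged
#'   `truncated` and counts are lower bounds.
#' @return a `path_result` (see [optimal_path()]) with `suboptimal_count`,
#'   `node_frequency` and `truncated` filled in, plus `paths` (list of label
#'   vectors) and `path_lengths`.
#' @export
suboptimal_paths <- function(graph, source, sink, offset = 20,
                             max_paths = 10000) {
  if (offset < 0) stop("offset must be nonnegative")
  res <- optimal_path(graph, source, sink)
  if (!res$found) return(res)
  si <- .node_index(graph, source); ti <- .node_index(graph, sink)
  names <- igraph::V(graph)$name
  bound <- res$length + offset
  if (si == ti) {
    res$suboptimal_count <- 0L
    res$node_frequency <- stats::setNames(1L, names[si])
    res$paths <- list(res$path); res$path_lengths <- 0L
    return(res)
  }
  w <- igraph::E(graph)$int_length
  to_sink <- igraph::distances(graph, v = ti, weights = w)[1, ]
  adj <- .adjacency_list(graph, w)
  found <- .bounded_dfs(adj, si, ti, bound, to_sink, max_paths)
  paths <- lapply(found$paths, function(p) names[p])
  res$paths <- paths
  res$path_lengths <- found$lengths
  res$suboptimal_count <- length(paths) - 1L
  res$truncated <- found$truncated
  freq <- table(unlist(paths))
  res$node_frequency <- sort(
    stats::setNames(as.integer(freq), names(freq)), decreasing = TRUE)
  res
}

.adjacency_list <- function(graph, w) {
  n <- igraph::vcount(graph)
  el <- igraph::as_edgelist(graph, names = FALSE)
  adj <- vector("list", n)
  for (v in seq_len(n)) adj[[v]] <- list(nb = integer(0), w = numeric(0))
  for (e in seq_len(nrow(el))) {
    a <- el[e, 1]; b <- el[e, 2]
    adj[[a]]$nb <- c(adj[[a]]$nb, b); adj[[a]]$w <- c(adj[[a]]$w, w[e])
    adj[[b]]$nb <- c(adj[[b]]$nb, a); adj[[b]]$w <- c(adj[[b]]$w, w[e])
  }
  adj
}

# iterative DFS over simple paths with admissible pruning:
# extend only while current length + lower bound to sink <= bound
.bounded_dfs <- function(adj, src, dst, bound, to_sink, max_paths) {
  paths <- list(); lengths <- numeric(0); truncated <- FALSE
  n <- length(adj)
  on_path <- logical(n)
  path <- integer(0)
  # explicit stack of (node, cumulative length, next-neighbour pointer)
  recurse <- function(v, len) {
    if (truncated) return()
    if (v == dst) {
      paths[[length(paths) + 1L]] <<- c(path, v)
      lengths[length(lengths) + 1L] <<- len
      if (length(paths) >= max_paths) truncated <<- TRUE
      return()
    }
    on_path[v] <<- TRUE
    path <<- c(path, v)
    nbs <- adj[[v]]$nb; ws <- adj[[v]]$w
    for (k in seq_along(nbs)) {
      u <- nbs[k]
      if (on_path[u]) next
      nl <- len + ws[k]
      if (nl + to_sink[u] <= bound) recurse(u, nl)
      if (truncated) break
    }
    on_path[v] <<- FALSE
    path <<- path[-length(path)]
  }
  recurse(src, 0)
  list(paths = paths, lengths = lengths, truncated = truncated)
}

#' @export
print.path_result <- function(x, ...) {
  if (!x$found) {
    cat("path_result:", x$source, "->", x$sink, ": no path\n")
    return(invisible(x))
  }
  cat("path_result:", paste(x$path, collapse = " -> "),
      sprintf("\n  length %d, %d residues", x$length, x$n_residues))
  if (!is.na(x$suboptimal_count)) {
    cat(sprintf(", %d suboptimal path(s)%s", x$suboptimal_count,
                if (isTRUE(x$truncated)) " [truncated]" else ""))
  }
  cat("\n")
  invisible(x)
}

#' Optimal/suboptimal path summary table
#'
#' One row per (source, sink) query: optimal integer length, number of
#' residues on the optimal path, and number of suboptimal paths within
#' `offset`. Disconnected queries are marked `found = FALSE`.
#'
#' @param graph a [build_graph()] result.
#' @param queries data.frame (or 2-column matrix) of source/sink labels.
#' @param offset suboptimal offset (default 20).
#' @param max_paths enumeration cap per query.
#' @return data.frame with columns `source`, `sink`, `found`, `length`,
#'   `n_residues`, `subopt`, `truncated`.
#' @export
path_table <- function(graph, queries, offset = 20, max_paths = 10000) {
  queries <- as.data.frame(queries)
  names(queries)[1:2] <- c("source", "sink")
  rows <- lapply(seq_len(nrow(queries)), function(r) {
    p <- suboptimal_paths(graph, queries$source[r], queries$sink[r],
                          offset = offset, max_paths = max_paths)
    data.frame(source = p$source, sink = p$sink, found = p$found,
               length = p$length, n_residues = p$n_residues,
               subopt = p$suboptimal_count, truncated = isTRUE(p$truncated),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Compare allosteric pathway strength between two systems
#'
#' Three criteria indicate a stronger allosteric relationship: shorter
#' optimal length, fewer involved residues, and more suboptimal paths. When
#' all informative criteria agree the verdict names the stronger system;
#' mixed signals yield `"ambiguous"` with the majority recorded (systems are
#' adjudicated narratively in that case); identical rows yield `"equal"`.
#'
#' @param row_a,row_b single [path_table()] rows (or lists with `length`,
#'   `n_residues`, `subopt`) for the same query in systems A and B.
#' @return list with `verdict` (`"stronger_in_a"`, `"stronger_in_b"`,
#'   `"ambiguous"` or `"equal"`), `votes` (+1 favours A on that criterion,
#'   -1 favours B, 0 tie) and `majority` (sign of the vote sum).
#' @export
compare_pathways <- function(row_a, row_b) {
  votes <- c(
    length = sign(row_b$length - row_a$length),       # shorter is stronger
    n_residues = sign(row_b$n_residues - row_a$n_residues),
    subopt = sign(row_a$subopt - row_b$subopt)        # more is stronger
  )
  nz <- votes[votes != 0]
  verdict <- if (length(nz) == 0) "equal"
  else if (all(nz > 0)) "stronger_in_a"
  else if (all(nz < 0)) "stronger_in_b"
  else "ambiguous"
  list(verdict = verdict, votes = votes, majority = sign(sum(votes)))
}

#' Export a residue graph as an edge-list table
#'
#' @param graph a [build_graph()] result.
#' @return data.frame with columns `node_i`, `node_j`, `abs_x`,
#'   `raw_weight`, `int_length`.
#' @export
graph_edge_table <- function(graph) {
  el <- igraph::as_edgelist(graph)
  data.frame(node_i = el[, 1], node_j = el[, 2],
             abs_x = igraph::E(graph)$abs_x,
             raw_weight = igraph::E(graph)$raw_weight,
             int_length = igraph::E(graph)$int_length,
             stringsAsFactors = FALSE)
}

#' Write a residue graph as GraphML
#'
#' @param graph a [build_graph()] result.
#' @param file output path.
#' @export
write_graphml <- function(graph, file) {
  g <- graph
  class(g) <- setdiff(class(g), "residue_graph")
  igraph::write_graph(g, file, format = "graphml")
  invisible(file)
}
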
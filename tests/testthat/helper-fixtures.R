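# Shared fixtures and independent oracles.

# a small multi-model PDB text, built in code
pdb_text <- function(models) {
  fmt <- function(serial, name, resname, chain, resno, x, y, z, el) {
    sprintf("ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            serial, name, resname, chain, resno, x, y, z, el)
  }
  blocks <- vapply(seq_along(models), function(m) {
    rows <- models[[m]]
    body <- paste(vapply(seq_len(nrow(rows)), function(i) {
      with(rows[i, ], fmt(serial, name, resname, chain, resno, x, y, z,
                          element))
    }, character(1)), collapse = "\n")
    if (length(models) > 1) {
      paste0(sprintf("MODEL     %4d\n", m), body, "\nENDMDL")
    } else body
  }, character(1))
  paste0(paste(blocks, collapse = "\n"), "\nEND\n")
}

tripeptide_atoms <- function(dx = 0) {
  data.frame(
    serial = 1:3, name = "CA", element = "C",
    resno = 1:3, resname = c("ALA", "GLY", "SER"), chain = "A",
    x = c(0, 3.8, 7.6) + dx, y = 0, z = 0, stringsAsFactors = FALSE
  )
}

# rotate row-vector coordinates by `deg` about the z axis, then translate
rigid_move <- function(m, deg = 0, shift = c(0, 0, 0)) {
  th <- deg * pi / 180
  rot <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  sweep(m %*% rot, 2, shift, FUN = "+")
}

# --- independent path oracle: plain recursive enumeration of ALL simple
# paths (no pruning, no bound), filtered afterwards -----------------------
enumerate_simple_paths <- function(edges, n, src, dst) {
  # edges: data.frame i, j, w (1-based, undirected)
  adj <- lapply(seq_len(n), function(v) {
    rows <- which(edges$i == v | edges$j == v)
    other <- ifelse(edges$i[rows] == v, edges$j[rows], edges$i[rows])
    list(nb = other, w = edges$w[rows])
  })
  out <- list()
  walk <- function(v, visited, len, path) {
    if (v == dst) {
      out[[length(out) + 1L]] <<- list(path = path, len = len)
      return()
    }
    for (k in seq_along(adj[[v]]$nb)) {
      u <- adj[[v]]$nb[k]
      if (visited[u]) next
      visited[u] <- TRUE
      walk(u, visited, len + adj[[v]]$w[k], c(path, u))
      visited[u] <- FALSE
    }
  }
  visited <- rep(FALSE, n); visited[src] <- TRUE
  walk(src, visited, 0, src)
  out
}

# package tie-break applied to an enumerated path set: minimal length, then
# fewest nodes, then lexicographic on the label sequence
oracle_optimal <- function(all_paths, labels) {
  lens <- vapply(all_paths, `[[`, numeric(1), "len")
  cand <- all_paths[lens == min(lens)]
  sizes <- vapply(cand, function(p) length(p$path), integer(1))
  cand <- cand[sizes == min(sizes)]
  keys <- vapply(cand, function(p) paste(labels[p$path], collapse = "\r"),
                 character(1))
  cand[[order(keys)[1]]]
}

# random connected graph with |X| edge magnitudes in (0.05, 1]
random_planted_graph <- function(n, seed) {
  set.seed(seed)
  repeat {
    pairs <- t(combn(n, 2))
    keep <- runif(nrow(pairs)) < 0.45
    if (sum(keep) == 0) next
    edges <- data.frame(i = pairs[keep, 1], j = pairs[keep, 2],
                        x = runif(sum(keep), 0.05, 1))
    g <- igraph::graph_from_edgelist(as.matrix(edges[, 1:2]),
                                     directed = FALSE)
    if (igraph::vcount(g) == n && igraph::is_connected(g)) return(edges)
  }
}

canonical_path_set <- function(paths) {
  sort(vapply(paths, paste, character(1), collapse = ">"))
}
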
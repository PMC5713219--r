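diamond_graph <- function() {
  # two branches 1-2-4 (|X| 0.9, 0.9) and 1-3-4 (|X| 0.5, 0.5)
  pg <- plant_path_graph(4, data.frame(i = c(1, 1, 2, 3), j = c(2, 3, 4, 4),
                                       x = c(0.9, 0.5, 0.9, 0.5)))
  build_graph(pg$correlation, pg$contacts)
}

test_that("edge lengths follow -ln|X| with x100 integer scaling", {
  pg <- plant_path_graph(2, data.frame(i = 1, j = 2, x = 0.5))
  g <- build_graph(pg$correlation, pg$contacts)
  et <- graph_edge_table(g)
  expect_equal(et$raw_weight, -log(0.5))
  expect_equal(et$int_length, 69)  # round(100 * 0.6931)

  pg1 <- plant_path_graph(2, data.frame(i = 1, j = 2, x = 1))
  expect_equal(graph_edge_table(
    build_graph(pg1$correlation, pg1$contacts))$int_length, 0)
})

test_that("contact pairs with zero correlation are dropped with a warning", {
  corr <- diag(3); corr[1, 2] <- corr[2, 1] <- 0.8
  contacts <- matrix(TRUE, 3, 3); diag(contacts) <- FALSE
  expect_warning(g <- build_graph(corr, contacts), "\\|X\\| = 0")
  expect_equal(igraph::ecount(g), 1)
  expect_error(build_graph(diag(4), contacts), "dimensions differ")
})

test_that("optimal path handles trivial, tied and disconnected cases", {
  g <- diamond_graph()
  p <- optimal_path(g, "N1", "N4")
  expect_equal(p$path, c("N1", "N2", "N4"))
  expect_equal(p$length, 22L)  # 2 x round(100 * -ln 0.9) = 2 x 11
  expect_equal(p$n_residues, 3)

  same <- optimal_path(g, "N2", "N2")
  expect_true(same$found)
  expect_equal(same$path, "N2")
  expect_equal(same$length, 0L)

  # disconnected pair: explicit no-path result, not an exception
  corr <- diag(4); corr[1, 2] <- corr[2, 1] <- 0.9
  corr[3, 4] <- corr[4, 3] <- 0.9
  contacts <- corr != 0 & row(corr) != col(corr)
  suppressWarnings(gd <- build_graph(corr, contacts))
  pd <- optimal_path(gd, 1, 3)
  expect_false(pd$found)
  expect_true(is.na(pd$length))

  # tie between equal branches is broken deterministically (lexicographic)
  pg <- plant_path_graph(4, data.frame(i = c(1, 1, 2, 3), j = c(2, 3, 4, 4),
                                       x = 0.5))
  gt <- build_graph(pg$correlation, pg$contacts)
  expect_equal(optimal_path(gt, "N1", "N4")$path, c("N1", "N2", "N4"))
})

test_that("suboptimal enumeration matches the diamond by hand", {
  g <- diamond_graph()
  # offset 0: the slow branch (length 138) is not co-optimal
  s0 <- suboptimal_paths(g, "N1", "N4", offset = 0)
  expect_equal(s0$suboptimal_count, 0)
  # wide offset admits the second branch
  s1 <- suboptimal_paths(g, "N1", "N4", offset = 138 - 22)
  expect_equal(s1$suboptimal_count, 1)
  expect_equal(sort(unname(s1$node_frequency[c("N1", "N4")])), c(2, 2))

  # equal branches at offset 0: exactly one co-optimal alternative
  pg <- plant_path_graph(4, data.frame(i = c(1, 1, 2, 3), j = c(2, 3, 4, 4),
                                       x = 0.5))
  ge <- build_graph(pg$correlation, pg$contacts)
  expect_equal(suboptimal_paths(ge, "N1", "N4", offset = 0)$suboptimal_count,
               1)
})

test_that("optimal and suboptimal paths equal brute-force enumeration", {
  n_graphs <- 100
  for (k in seq_len(n_graphs)) {
    n <- 4 + (k %% 7)  # 4..10 nodes
    edges <- random_planted_graph(n, seed = 1000 + k)
    pg <- plant_path_graph(n, edges)
    g <- build_graph(pg$correlation, pg$contacts)
    et <- graph_edge_table(g)
    idx <- function(lbl) as.integer(sub("N", "", lbl))
    oracle_edges <- data.frame(i = idx(et$node_i), j = idx(et$node_j),
                               w = et$int_length)
    src <- 1; dst <- n
    all_paths <- enumerate_simple_paths(oracle_edges, n, src, dst)
    labels <- paste0("N", seq_len(n))

    p <- optimal_path(g, labels[src], labels[dst])
    best <- oracle_optimal(all_paths, labels)
    expect_equal(p$length, as.integer(best$len))
    expect_equal(p$path, labels[best$path])

    s <- suboptimal_paths(g, labels[src], labels[dst], offset = 20)
    keep <- vapply(all_paths, function(q) q$len <= best$len + 20,
                   logical(1))
    oracle_set <- canonical_path_set(
      lapply(all_paths[keep], function(q) labels[q$path]))
    expect_equal(canonical_path_set(s$paths), oracle_set)
    expect_equal(s$suboptimal_count, sum(keep) - 1L)
  }
})

test_that("suboptimal count grows monotonically with the offset", {
  edges <- random_planted_graph(8, seed = 77)
  pg <- plant_path_graph(8, edges)
  g <- build_graph(pg$correlation, pg$contacts)
  counts <- vapply(c(0, 10, 20, 50, 100, 200), function(off) {
    suboptimal_paths(g, "N1", "N8", offset = off)$suboptimal_count
  }, integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("strengthening a coupling never lengthens optimal paths", {
  edges <- random_planted_graph(7, seed = 55)
  pg <- plant_path_graph(7, edges)
  g1 <- build_graph(pg$correlation, pg$contacts)
  stronger <- edges; stronger$x <- pmin(1, stronger$x * 1.5)
  pg2 <- plant_path_graph(7, stronger)
  g2 <- build_graph(pg2$correlation, pg2$contacts)
  for (dst in 2:7) {
    l1 <- optimal_path(g1, "N1", paste0("N", dst))$length
    l2 <- optimal_path(g2, "N1", paste0("N", dst))$length
    expect_lte(l2, l1)
  }
})

test_that("the enumeration cap truncates with a flag", {
  # complete graph on 8 nodes with |X| = 1 everywhere: every simple path
  # has length 0, so the path count explodes
  pairs <- t(combn(8, 2))
  pg <- plant_path_graph(8, data.frame(i = pairs[, 1], j = pairs[, 2], x = 1))
  g <- build_graph(pg$correlation, pg$contacts)
  s <- suboptimal_paths(g, "N1", "N8", offset = 0, max_paths = 50)
  expect_true(s$truncated)
  expect_equal(length(s$paths), 50)
})

test_that("contact maps respect cutoff, occupancy and neighbour exclusion", {
  ch <- make_chain(6, "line")  # 3.8 A spacing
  base <- as.vector(t(structure_coords(ch)))
  tr <- md_trajectory(ch, rbind(base, base, base, base))
  cm <- contact_map(tr, mode = "calpha", cutoff = 8.0,
                    exclude_neighbors = 2)
  # |i-j| = 2 is 7.6 A (within cutoff) but excluded as a neighbour
  expect_false(cm$map[1, 3])
  expect_false(cm$map[1, 2])
  expect_false(any(cm$map))  # |i-j| >= 3 is 11.4 A, beyond cutoff
  cm1 <- contact_map(tr, mode = "calpha", cutoff = 8.0,
                     exclude_neighbors = 1)
  expect_true(cm1$map[1, 3])
  expect_true(isSymmetric(cm1$map * 1))
  expect_false(any(diag(cm1$map)))

  # occupancy: within cutoff in only 2 of 4 frames < 75%
  far <- base; far[atom2xyz(3)] <- far[atom2xyz(3)] + c(100, 0, 0)
  tr2 <- md_trajectory(ch, rbind(base, base, far, far))
  cm2 <- contact_map(tr2, mode = "calpha", cutoff = 8.0,
                     exclude_neighbors = 1, occupancy = 0.75)
  expect_false(cm2$map[1, 3])
  cm3 <- contact_map(tr2, mode = "calpha", cutoff = 8.0,
                     exclude_neighbors = 1, occupancy = 0.5)
  expect_true(cm3$map[1, 3])
})

test_that("path tables summarise queries and mark missing paths", {
  pg <- plant_path_graph(3, data.frame(i = c(1, 2), j = c(2, 3), x = 1))
  g <- build_graph(pg$correlation, pg$contacts)
  tab <- path_table(g, data.frame(source = "N1", sink = "N3"))
  expect_equal(tab$length, 0L)
  expect_equal(tab$n_residues, 3L)
  expect_equal(tab$subopt, 0L)

  g4 <- diamond_graph()
  t4 <- path_table(g4, data.frame(source = "N1", sink = "N4"), offset = 200)
  expect_equal(t4$length, 22L)
  expect_equal(t4$subopt, 1L)

  corr <- diag(3); corr[1, 2] <- corr[2, 1] <- 0.9
  contacts <- corr != 0 & row(corr) != col(corr)
  gd <- build_graph(corr, contacts)
  td <- path_table(gd, data.frame(source = c("N1"), sink = c("N3")))
  expect_false(td$found)
})

test_that("the three-criterion strength rule matches its narrative use", {
  ref <- hras_ns1_path_table()
  row_of <- function(r, side) {
    list(length = ref[[paste0("length_", side)]][r],
         n_residues = ref[[paste0("n_residues_", side)]][r],
         subopt = ref[[paste0("subopt_", side)]][r])
  }
  # unanimous rows: shorter, fewer residues, more suboptimal paths in wt
  for (r in 1:2) {
    v <- compare_pathways(row_of(r, "wt"), row_of(r, "r135k"))
    expect_equal(v$verdict, "stronger_in_a")
  }
  # mixed signals (wt length slightly longer): ambiguous, majority to wt
  for (r in 3:4) {
    v <- compare_pathways(row_of(r, "wt"), row_of(r, "r135k"))
    expect_equal(v$verdict, "ambiguous")
    expect_equal(v$majority, 1)
  }
  ident <- list(length = 10, n_residues = 3, subopt = 2)
  expect_equal(compare_pathways(ident, ident)$verdict, "equal")
})
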
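make_planted_traj <- function(corr, n_frames, seed, n_res = nrow(corr),
                              amplitude = 1) {
  sample_correlated_trajectory(
    planted_model(make_chain(n_res, "line"), corr, n_frames = n_frames,
                  seed = seed, amplitude = amplitude))
}

test_that("perfectly coupled and antiphase motions give +1/-1", {
  s <- md_structure(tripeptide_atoms())
  base <- as.vector(t(structure_coords(s)))
  # all residues share one displacement series
  shift <- c(0.3, -0.2, 0.5, 0.3, -0.2, 0.5, 0.3, -0.2, 0.5)
  frames <- rbind(base, base + shift, base - shift, base + 2 * shift)
  x <- dccm(md_trajectory(s, frames), superpose = FALSE)
  expect_equal(unclass(x), matrix(1, 3, 3), ignore_attr = TRUE,
               tolerance = 1e-9)

  # residue 2 in exact antiphase with residues 1 and 3 along x
  anti <- rbind(base + c(1, 0, 0, -1, 0, 0, 1, 0, 0),
                base - c(1, 0, 0, -1, 0, 0, 1, 0, 0))
  xa <- dccm(md_trajectory(s, anti), superpose = FALSE)
  expect_equal(xa[1, 2], -1, tolerance = 1e-9)
  expect_equal(xa[1, 3], 1, tolerance = 1e-9)
})

test_that("planted rho = 0.5 is recovered within sampling error", {
  corr <- diag(6); corr[2, 5] <- corr[5, 2] <- 0.5
  tr <- make_planted_traj(corr, 20000, seed = 1)
  x <- dccm(tr, superpose = FALSE)
  expect_lt(abs(x[2, 5] - 0.5), 0.03)
})

test_that("DCCM is symmetric with unit diagonal and bounded entries", {
  corr <- outer(1:7, 1:7, function(i, j) 0.6^abs(i - j))
  x <- dccm(make_planted_traj(corr, 500, seed = 6), superpose = FALSE)
  expect_true(isSymmetric(unclass(x)))
  expect_equal(unname(diag(x)), rep(1, 7))
  expect_true(all(x >= -1 & x <= 1))
})

test_that("zero-variance residues produce defined output plus a warning", {
  s <- md_structure(tripeptide_atoms())
  base <- as.vector(t(structure_coords(s)))
  frames <- rbind(base, base + c(1, 0, 0, 0, 0, 0, -1, 0, 0))  # res 2 static
  expect_warning(x <- dccm(md_trajectory(s, frames), superpose = FALSE),
                 "zero-variance")
  expect_equal(x[2, 1], 0)
  expect_equal(x[2, 2], 1)
  expect_false(any(is.na(x)))
})

test_that("DCCM is invariant to uniform scaling of displacements", {
  corr <- diag(5); corr[1, 3] <- corr[3, 1] <- -0.7
  x1 <- dccm(make_planted_traj(corr, 300, seed = 9, amplitude = 0.5),
             superpose = FALSE)
  x2 <- dccm(make_planted_traj(corr, 300, seed = 9, amplitude = 5),
             superpose = FALSE)
  expect_equal(unclass(x1), unclass(x2), tolerance = 1e-9)
})

test_that("thresholding zeroes weak entries and keeps the diagonal", {
  m <- diag(3)
  m[1, 2] <- m[2, 1] <- 0.29
  m[1, 3] <- m[3, 1] <- -0.35
  t3 <- threshold_dccm(m, 0.3)
  expect_equal(t3[1, 2], 0)      # below the 0.3 magnitude gate
  expect_equal(t3[1, 3], -0.35)  # kept, sign preserved
  expect_equal(diag(t3), rep(1, 3))
  expect_equal(threshold_dccm(m, 0), m)  # cutoff 0 is the identity
  expect_error(threshold_dccm(m, 1.5), "\\[0, 1\\]")
})

test_that("DCCM agrees with correlations from the 3N covariance blocks", {
  corr <- outer(1:5, 1:5, function(i, j) 0.5^abs(i - j))
  tr <- make_planted_traj(corr, 400, seed = 13)
  x <- dccm(tr, superpose = FALSE)
  p <- trajectory_pca(tr, superpose = FALSE)
  z <- p$covariance
  n <- 5
  for (i in 1:n) for (j in 1:n) {
    bi <- (3 * i - 2):(3 * i); bj <- (3 * j - 2):(3 * j)
    num <- sum(diag(z[bi, bj, drop = FALSE]))
    den <- sqrt(sum(diag(z[bi, bi])) * sum(diag(z[bj, bj])))
    expect_equal(x[i, j], num / den, tolerance = 1e-9)
  }
})

test_that("DCCM matches the bio3d implementation on the same coordinates", {
  corr <- outer(1:6, 1:6, function(i, j) 0.4^abs(i - j))
  tr <- make_planted_traj(corr, 250, seed = 17)
  mine <- dccm(tr, superpose = FALSE)
  theirs <- bio3d::dccm.xyz(tr$xyz)
  expect_equal(unclass(mine), unclass(theirs), ignore_attr = TRUE,
               tolerance = 1e-9)
})

test_that("PCA recovers a single planted mode and its spectrum identities", {
  set.seed(31)
  n <- 10
  dirs <- matrix(rnorm(3 * n), n, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  model <- planted_model(make_chain(n, "helix"),
                         matrix(1, n, n),  # one common latent factor
                         n_frames = 3000, seed = 31, amplitude = 1,
                         directions = dirs)
  tr <- sample_correlated_trajectory(model)
  p <- trajectory_pca(tr, superpose = FALSE)
  planted <- as.vector(t(dirs)) / sqrt(n)
  cosine <- abs(sum(p$vectors[, 1] * planted))
  expect_gte(cosine, 0.99)
  # trace identity and eigenvalue ordering
  expect_equal(sum(p$values), sum(diag(p$covariance)),
               tolerance = 1e-6 * abs(sum(p$values)))
  expect_true(all(diff(p$values) <= 1e-12))
  expect_true(all(p$values > -1e-9))
  # one-mode trajectory: PC2 variance is negligible
  scores <- pca_project(tr, p, k = 2, superpose = FALSE)
  expect_lt(stats::var(scores[, 2]) / stats::var(scores[, 1]), 0.01)
  # score variance reproduces the eigenvalue (population convention)
  pop_var <- function(v) mean((v - mean(v))^2)
  expect_equal(pop_var(scores[, 1]), p$values[1], tolerance = 1e-9)
})

test_that("a static trajectory has an all-zero spectrum", {
  s <- md_structure(tripeptide_atoms())
  base <- as.vector(t(structure_coords(s)))
  p <- trajectory_pca(md_trajectory(s, rbind(base, base, base)),
                      superpose = FALSE)
  expect_equal(p$values, rep(0, 9), tolerance = 1e-12)
})

test_that("projection of the mean structure is the zero vector", {
  corr <- diag(4)
  tr <- make_planted_traj(corr, 100, seed = 2)
  p <- trajectory_pca(tr, superpose = FALSE)
  mean_traj <- md_trajectory(tr$topology, as.vector(t(p$mean_coords)))
  sc <- pca_project(mean_traj, p, k = 2, superpose = FALSE)
  expect_equal(as.numeric(sc), c(0, 0), tolerance = 1e-9)
})
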
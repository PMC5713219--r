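test_that("two-particle nonbonded energies match closed forms", {
  # at r = sigma with zero charge both terms vanish
  a <- make_two_particle_system(0, 0, 0.3, 3.0, 3.0)
  e <- nonbonded_energy(a$structure, a$parameters)
  expect_equal(e$E_vdw, 0, tolerance = 1e-12)
  expect_equal(e$E_ele, 0)

  # LJ minimum at r = 2^(1/6) sigma is exactly -eps
  b <- make_two_particle_system(0, 0, 0.2, 3.0, 2^(1 / 6) * 3.0)
  expect_equal(nonbonded_energy(b$structure, b$parameters)$E_vdw, -0.2,
               tolerance = 1e-12)

  # unit charges at 3.320637 A give 100 kcal/mol (Coulomb constant check)
  c_ <- make_two_particle_system(1, 1, 0, 3.0, 3.320637)
  expect_equal(nonbonded_energy(c_$structure, c_$parameters)$E_ele, 100,
               tolerance = 1e-9)
})

test_that("cutoff truncation and exclusions behave as configured", {
  sys <- make_two_particle_system(1, 1, 0.2, 3.0, 12.0)
  e <- nonbonded_energy(sys$structure, sys$parameters, cutoff = 10)
  expect_equal(e$E_ele, 0)  # beyond cutoff
  e2 <- nonbonded_energy(sys$structure, sys$parameters, cutoff = 20)
  expect_gt(e2$E_ele, 0)
  e3 <- nonbonded_energy(sys$structure, sys$parameters, cutoff = 20,
                         exclusions = cbind(1, 2))
  expect_equal(e3$E_ele, 0)
  bad_par <- sys$parameters[1, , drop = FALSE]
  expect_error(nonbonded_energy(sys$structure, bad_par), "missing parameters")
})

test_that("multi-particle energies match an independent double loop", {
  set.seed(12)
  n <- 6
  atoms <- data.frame(serial = 1:n, name = paste0("P", 1:n), element = "X",
                      resno = 1:n, resname = "LJP", chain = "A",
                      x = runif(n, 0, 6), y = runif(n, 0, 6),
                      z = runif(n, 0, 6))
  s <- md_structure(atoms)
  par <- data.frame(serial = 1:n, charge = runif(n, -1, 1),
                    eps = runif(n, 0.05, 0.3), sigma = runif(n, 2.5, 3.5))
  got <- nonbonded_energy(s, par, cutoff = 1e6)
  # brute force, written independently of the implementation
  ev <- 0; ee <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    r <- sqrt(sum((atoms[i, c("x", "y", "z")] - atoms[j, c("x", "y", "z")])^2))
    ee <- ee + 332.0637 * par$charge[i] * par$charge[j] / r
    sij <- (par$sigma[i] + par$sigma[j]) / 2
    eij <- sqrt(par$eps[i] * par$eps[j])
    ev <- ev + 4 * eij * ((sij / r)^12 - (sij / r)^6)
  }
  expect_equal(got$E_vdw, ev, tolerance = 1e-9)
  expect_equal(got$E_ele, ee, tolerance = 1e-9)
})

test_that("SASA reproduces closed-form sphere areas", {
  one <- md_structure(data.frame(serial = 1, name = "X1", element = "X",
                                 resno = 1, resname = "UNK", chain = "A",
                                 x = 0, y = 0, z = 0))
  got <- sasa(one, probe = 1.4, radii = c(X = 1.6))
  expect_equal(got$total, 4 * pi * 3.0^2, tolerance = 0.01 * 4 * pi * 9)

  # two atoms far apart: additivity
  two <- md_structure(data.frame(serial = 1:2, name = c("X1", "X2"),
                                 element = "X", resno = 1:2, resname = "UNK",
                                 chain = "A", x = c(0, 100), y = 0, z = 0))
  got2 <- sasa(two, probe = 1.4, radii = c(X = 1.6))
  expect_equal(got2$total, 2 * got$total, tolerance = 1e-6)

  # an atom caged by a tight octahedron of large spheres is buried
  cage <- 2.0
  caged <- md_structure(data.frame(
    serial = 1:7, name = paste0("X", 1:7), element = "X",
    resno = 1:7, resname = "UNK", chain = "A",
    x = c(0, cage, -cage, 0, 0, 0, 0),
    y = c(0, 0, 0, cage, -cage, 0, 0),
    z = c(0, 0, 0, 0, 0, cage, -cage)))
  got3 <- sasa(caged, probe = 1.4, radii = rep(c(1.0, 3.0), c(1, 6)))
  expect_equal(got3$atom_area[1], 0)

  expect_error(sasa(one), "no radius")
  # convergence: doubling the point count moves totals by < 0.5%
  c60 <- sasa(caged, probe = 1.4, radii = rep(c(1.0, 3.0), c(1, 6)),
              n_points = 480)$total
  c120 <- sasa(caged, probe = 1.4, radii = rep(c(1.0, 3.0), c(1, 6)),
               n_points = 960)$total
  expect_lt(abs(c120 - c60) / c120, 0.005)
})

test_that("nonpolar solvation is gamma * SASA + b", {
  expect_equal(nonpolar_solvation(0), 0.92)
  expect_equal(nonpolar_solvation(1000), 6.34)
  expect_equal(nonpolar_solvation(500, gamma = 0), 0.92)
  expect_error(nonpolar_solvation(-1), "nonnegative")
})

test_that("the binding ledger reproduces the reference totals", {
  ref <- hras_ns1_energy_table()
  comp <- function(sys, term) ref$mean[ref$system == sys & ref$term == term]
  for (sys in c("wt", "r135k")) {
    bs <- delta_binding_summary(
      E_vdw = comp(sys, "E_vdw"), E_ele = comp(sys, "E_ele"),
      G_polar = comp(sys, "G_polar"), G_nonpolar = comp(sys, "G_nonpolar"))
    val <- function(t) bs$summary$mean[bs$summary$term == t]
    expect_equal(val("dG_gas"), comp(sys, "dG_gas"), tolerance = 0.011)
    expect_equal(val("dG_binding"), comp(sys, "dG_binding"),
                 tolerance = 0.011)
    # ledger closure: component rows sum to the binding total exactly
    expect_equal(val("dE_vdw") + val("dE_ele") + val("dE_int") +
                   val("dG_gb") + val("dG_surf"), val("dG_binding"),
                 tolerance = 1e-12)
  }
})

test_that("per-frame deltas close the ledger identity exactly", {
  set.seed(44)
  f <- 20
  mk <- function() data.frame(E_vdw = rnorm(f), E_ele = rnorm(f),
                              E_int = rnorm(f), G_polar = rnorm(f),
                              G_nonpolar = rnorm(f))
  bs <- binding_summary(energy_components("complex", mk()),
                        energy_components("receptor", mk()),
                        energy_components("ligand", mk()),
                        entropy_term = 1.5)
  d <- bs$deltas
  expect_equal(d$dG_binding,
               d$dE_vdw + d$dE_ele + d$dE_int + d$dG_gb + d$dG_surf - 1.5,
               tolerance = 1e-12)
  expect_equal(d$dG_gas, d$dE_vdw + d$dE_ele + d$dE_int, tolerance = 1e-12)
  # all-zero components give an all-zero summary
  zero <- mk(); zero[] <- 0
  bz <- binding_summary(energy_components("complex", zero),
                        energy_components("receptor", zero),
                        energy_components("ligand", zero))
  expect_equal(bz$summary$mean, rep(0, 8))
  # frame-count mismatch is an error
  expect_error(binding_summary(energy_components("complex", mk()),
                               energy_components("receptor", mk()[1:5, ]),
                               energy_components("ligand", mk())),
               "frame-count mismatch")
})

test_that("residue decomposition differences and flags match the reference", {
  ref <- hras_ns1_residue_table()
  wt <- data.frame(residue = ref$residue, mean = ref$mean_wt, sd = ref$sd_wt)
  mut <- data.frame(residue = ref$residue, mean = ref$mean_r135k,
                    sd = ref$sd_r135k)
  dec <- residue_decomposition(wt, mut, threshold = 0.3)
  expect_equal(dec$difference[dec$residue == "D29"], 1.69, tolerance = 0.005)
  expect_equal(dec$difference[dec$residue == "R135K"], 7.81,
               tolerance = 0.005)
  # 0.31 is strictly above the 0.3 threshold and must flag
  expect_equal(dec$difference[dec$residue == "I142"], 0.31,
               tolerance = 0.005)
  expect_true(all(dec$flagged))

  # identical inputs: nothing flagged; exactly-0.30 difference not flagged
  same <- residue_decomposition(wt, wt)
  expect_true(all(same$difference == 0))
  expect_false(any(same$flagged))
  w2 <- data.frame(residue = "X1", mean = 0)
  m2 <- data.frame(residue = "X1", mean = 0.3)
  expect_false(residue_decomposition(w2, m2)$flagged)

  # residue present in only one system: reported, never flagged
  lop <- residue_decomposition(wt, rbind(mut,
                                         data.frame(residue = "Z9",
                                                    mean = 5, sd = 1)))
  z <- lop[lop$residue == "Z9", ]
  expect_true(is.na(z$difference))
  expect_false(z$flagged)
})
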
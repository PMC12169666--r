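test_that("bonded term primitives evaluate their closed forms", {
  ## quartic bond
  expect_equal(bond_energy(0.1443, 0.1443, 1e6), 0)
  expect_equal(bond_energy(0.11, 0.10, 1e7), 11.025, tolerance = 1e-12)
  expect_equal(bond_energy(0.2, 0.1443, 1e7, constrained = TRUE), 0)
  expect_error(bond_energy(-0.1, 0.1, 1), "positive")

  ## cosine-harmonic angle
  expect_equal(angle_energy(130.22, 130.22, 3772.45), 0)
  expect_equal(angle_energy(135, 130.22, 3772.45), 7.10694397545,
               tolerance = 1e-10)
  expect_error(angle_energy(190, 100, 1), "range")

  ## harmonic improper (per rad^2), even in the deviation
  expect_equal(improper_energy(0, 0, 502.08), 0)
  expect_equal(improper_energy(5, 0, 502.08), 1.91177892658, tolerance = 1e-10)
  expect_equal(improper_energy(-5, 0, 502.08), improper_energy(5, 0, 502.08))
})

test_that("dihedral potentials evaluate their closed forms", {
  term <- data.frame(m = 2, phi0 = 0, k = -42.3)
  expect_equal(gromos_dihedral_energy(90, term), 0, tolerance = 1e-12)
  expect_equal(gromos_dihedral_energy(0, term), -84.6)
  expect_equal(gromos_dihedral_energy(33, data.frame(m = 3, phi0 = 0, k = 0)), 0)
  expect_error(gromos_dihedral_energy(0, data.frame(m = 0, phi0 = 0, k = 1)),
               "multiplicity")

  c_h2o2 <- get_topology("H2O2")$dihedrals[[1]]$c
  expect_equal(rb_dihedral_energy(0, c_h2o2), 30.45110235, tolerance = 1e-8)
  expect_equal(rb_dihedral_energy(180, c_h2o2), 4.50880235, tolerance = 1e-8)
  c_hno3 <- get_topology("HNO3")$dihedrals[[1]]$c
  expect_equal(rb_dihedral_energy(90, c_hno3), 32.758724, tolerance = 1e-10)
})

test_that("pair nonbonded energy composes LJ and Coulomb correctly", {
  expect_equal(pair_nonbonded_energy(0.5, 0, 0, 0.5, -0.5), -69.467729,
               tolerance = 1e-9)
  c6 <- combine_c6("OP", "OP"); c12 <- combine_c12("OP", "OP")
  expect_equal(pair_nonbonded_energy(0.3, c6, c12, 0, 0), 0.245731559289,
               tolerance = 1e-9)
  expect_lt(abs(pair_nonbonded_energy(50, c6, c12, 0, 0)), 1e-9)
  expect_error(pair_nonbonded_energy(0, 1, 1, 0, 0), "positive")
})

test_that("whole-molecule energies sit at zero for reference geometries", {
  ## H2O2 at theta0 and the torsional minimum: everything at its minimum and
  ## all intramolecular nonbonded excluded by the RB rule
  top <- get_topology("H2O2")
  conf <- build_conformation(top, reference_internals(top, dihedrals = 112.5))
  e <- molecule_energy(top, conf)
  expect_lt(abs(e$total), 1e-3)
  expect_equal(e$lj_14 + e$coulomb_14 + e$lj_intra + e$coulomb_intra, 0)

  ## HNO3 planar reference: all terms at minima, no included pairs
  hno3 <- get_topology("HNO3")
  int <- reference_internals(hno3, dihedrals = 0)
  int["dih_2_1_3_4"] <- 180  # place the O(H) branch planar-trans
  int["dih_1_3_4_5"] <- 180  # ONOH trans
  conf3 <- build_conformation(hno3, int)
  e3 <- molecule_energy(hno3, conf3)
  expect_lt(abs(e3$angle + e3$improper), 0.2)  # theta0 sum 360.02 deg: tiny strain
  expect_equal(e3$lj_14 + e3$coulomb_14 + e3$lj_intra + e3$coulomb_intra, 0)

  ## HOONO has live 1-4 and 1-5 electrostatics
  hoono <- get_topology("HOONO")
  c5 <- build_conformation(hoono, reference_internals(hoono, dihedrals = 0))
  e5 <- molecule_energy(hoono, c5)
  expect_true(e5$coulomb_14 != 0)
  expect_true(e5$coulomb_intra != 0)
})

test_that("energy breakdown total equals the component sum", {
  set.seed(7)
  for (id in c("HOONO", "N2O4", "HNO3")) {
    top <- get_topology(id)
    e <- molecule_energy(top, random_conformation(top))
    comps <- e$bond + e$angle + e$improper + e$proper_dihedral +
      e$lj_14 + e$coulomb_14 + e$lj_intra + e$coulomb_intra
    expect_equal(e$total, comps, tolerance = 1e-9)
  }
})

test_that("molecule_energy matches the brute-force pair-enumeration oracle", {
  set.seed(42)
  for (id in list_species()) {
    top <- get_topology(id)
    for (rep in 1:5) {
      conf <- random_conformation(top)
      e_impl <- molecule_energy(top, conf)$total
      e_oracle <- oracle_energy(top, conf$xyz)
      expect_equal(e_impl, e_oracle, tolerance = 1e-9, info = id)
    }
  }
})

test_that("energy is invariant under rigid rotation and translation", {
  set.seed(11)
  top <- get_topology("HOONO")
  conf <- random_conformation(top)
  e0 <- molecule_energy(top, conf)$total
  for (rep in 1:3) {
    ## random rotation via QR of a Gaussian matrix
    M <- matrix(stats::rnorm(9), 3)
    Q <- qr.Q(qr(M))
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    x2 <- conf$xyz %*% Q + matrix(stats::runif(3, -5, 5),
                                  nrow(conf$xyz), 3, byrow = TRUE)
    e2 <- molecule_energy(top, x2)$total
    expect_equal(e2, e0, tolerance = 1e-9 * max(1, abs(e0)))
  }
})

test_that("HNO3 torsional term equals the analytic C0 sin^2 form", {
  c_hno3 <- get_topology("HNO3")$dihedrals[[1]]$c
  phi <- seq(-180, 180, by = 2.5)
  v <- rb_dihedral_energy(phi, c_hno3)
  expect_equal(v, c_hno3[1] * sin(pi / 180 * (phi - 180))^2,
               tolerance = 1e-9)
})
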
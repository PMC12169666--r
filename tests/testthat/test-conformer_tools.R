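test_that("build_conformation and measure_internals are inverse maps", {
  set.seed(3)
  for (id in c("HOONO", "HNO3", "N2O4", "ONOO-")) {
    top <- get_topology(id)
    for (rep in 1:4) {
      int <- reference_internals(top, dihedrals = 0)
      for (nm in names(int)) {
        int[nm] <- if (startsWith(nm, "ang_"))
          stats::runif(1, 30, 150) else stats::runif(1, -179, 179)
      }
      conf <- build_conformation(top, int)
      back <- measure_internals(top, conf)
      expect_equal(back[names(int)], int, tolerance = 1e-6)
    }
  }
})

test_that("measure_dihedral follows the signed IUPAC convention", {
  cis <- rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))
  expect_equal(measure_dihedral(cis, 1, 2, 3, 4), 0)
  trans <- rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0))
  expect_equal(abs(measure_dihedral(trans, 1, 2, 3, 4)), 180)
  skew <- rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 0.5, 0.6))
  phi <- measure_dihedral(skew, 1, 2, 3, 4)
  mirror <- skew; mirror[, 3] <- -mirror[, 3]
  expect_equal(measure_dihedral(mirror, 1, 2, 3, 4), -phi)
  lin <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0))
  expect_error(measure_dihedral(lin, 1, 2, 3, 4), "collinear")
  expect_error(measure_dihedral(cis, 1, 2, 3, 3), "distinct")
})

test_that("degenerate placement angles are rejected", {
  top <- get_topology("HOONO")
  int <- reference_internals(top, dihedrals = 0)
  int["ang_4_3_2"] <- 180
  expect_error(build_conformation(top, int), "degenerate")
})

test_that("H2O2 minimizes to its skewed equilibrium from a distorted start", {
  top <- get_topology("H2O2")
  res <- minimize_rigid_bonds(top, reference_internals(top, dihedrals = 60))
  expect_true(res$converged)
  expect_equal(unname(abs(res$dihedrals["HOOH"])), 112.5, tolerance = 0.1)
  ## the trace never leaves the rigid-bond manifold: bonds stay at b0
  xyz <- res$conformation$xyz
  b <- top$bonds
  for (k in seq_len(nrow(b)))
    expect_equal(sqrt(sum((xyz[b$i[k], ] - xyz[b$j[k], ])^2)), b$b0[k],
                 tolerance = 1e-9)
})

test_that("HNO3 relaxes to a planar minimum from a puckered start", {
  top <- get_topology("HNO3")
  int <- reference_internals(top, dihedrals = 0)
  int["dih_2_1_3_4"] <- 170   # 10-degree pucker of the NO3 fragment
  int["dih_1_3_4_5"] <- 170
  res <- minimize_rigid_bonds(top, int)
  expect_true(res$converged)
  xi <- measure_dihedral(res$conformation$xyz, 3, 1, 2, 4)
  expect_lt(abs(xi), 1e-3)
  expect_equal(unname(abs(res$dihedrals["ONOH"])), 180, tolerance = 1e-3)
})

test_that("all-planar HOONO starts are stationary by symmetry", {
  top <- get_topology("HOONO")
  for (dd in list(c(0, 180), c(180, 0), c(180, 180))) {
    int <- reference_internals(top)
    int["dih_1_2_3_4"] <- dd[1]; int["dih_2_3_4_5"] <- dd[2]
    f <- function(p) {
      int2 <- int
      int2[c("dih_1_2_3_4", "dih_2_3_4_5")] <- p
      molecule_energy(top, build_conformation(top, int2))$total
    }
    g <- pracma::grad(f, dd, heps = 1e-5)
    expect_lt(max(abs(g)), 1e-6)
  }
})

test_that("minimization converges with a tight gradient and flags escapes", {
  top <- get_topology("HOONO")
  specs <- hoono_conformer_specs(top)
  tab <- conformer_table(top, specs)
  expect_true(all(tab$converged))
  res <- attr(tab, "results")
  for (r in res) expect_lt(r$grad_norm, 1e-6)
  ## an unrestrained start deep in the gauche region escapes to the perp
  ## basin and is flagged
  free_gauche <- list(label = "gauche-free",
                      internal = specs[[2]]$internal,
                      pin_dihedrals = list())
  tab2 <- conformer_table(top, list(specs[[1]], free_gauche))
  expect_true(tab2$basin_escape[2])
})

test_that("the conformer table reproduces the published classical values", {
  top <- get_topology("HOONO")
  tab <- conformer_table(top, hoono_conformer_specs(top))
  ref <- c("cis-cis" = 0, "cis-gauche" = 3.4, "cis-perp" = 1.4,
           "cis-trans" = 12.3, "perp-perp" = 55.1, "trans-cis" = 25.0,
           "trans-perp" = 13.4, "trans-trans" = 21.0)
  for (nm in names(ref))
    expect_equal(tab$delta_e[tab$label == nm], ref[[nm]], tolerance = 0.5,
                 info = nm)
  ## freely minimized dihedrals within 3 degrees of the published ones
  expect_equal(abs(tab$NOOH[tab$label == "trans-perp"]), 105, tolerance = 3)
  expect_equal(abs(tab$ONOO[tab$label == "trans-perp"]), 179.5, tolerance = 3)
  expect_equal(abs(tab$NOOH[tab$label == "cis-perp"]), 90, tolerance = 3)
  ## minimized cis-cis angles match the published classical geometry
  res <- attr(tab, "results")[[1]]
  expect_equal(unname(res$angles), c(114.6, 112.4, 99.8), tolerance = 0.15)
})

test_that("torsion scans agree with direct term evaluation", {
  onoo <- get_topology("ONOO-")
  prof <- torsion_scan(onoo, c(1, 2, 3, 4), seq(-180, 180, by = 10))
  expect_equal(prof$energy[prof$phi == 180] - prof$energy[prof$phi == 0],
               15.0, tolerance = 1e-9)
  ## scan values equal the topology's dihedral term evaluated directly
  d <- onoo$dihedrals[[1]]
  expect_equal(prof$energy, gromos_dihedral_energy(prof$phi, d$terms),
               tolerance = 1e-12)

  hno2 <- get_topology("HNO2")
  p2 <- torsion_scan(hno2, c(1, 2, 3, 4), seq(-180, 180, by = 5))
  expect_equal(p2$energy[p2$phi == 90], 38.651923, tolerance = 1e-9)
  expect_equal(min(p2$energy), p2$energy[p2$phi == 180], tolerance = 1e-12)
  expect_error(torsion_scan(hno2, c(2, 3, 4, 1), c(0, 10)), "no dihedral")
  expect_error(torsion_scan(hno2, c(1, 2, 3, 4), c(10, 0)), "increasing")
})

test_that("relaxed scans expose the 1-4 electrostatics of peroxynitrite", {
  ## the bare adjusted torsion places trans 15 kJ/mol above cis, but in the
  ## full gas-phase model the 1-4 Coulomb repulsion between the charged
  ## terminal oxygens destabilizes the compact cis state and inverts the
  ## ordering: a documented limitation of the classical point-charge model
  top <- get_topology("ONOO-")
  prof <- torsion_scan(top, c(1, 2, 3, 4), c(0, 90, 180),
                       mode = "full_molecule_relaxed")
  expect_true(all(prof$converged))
  gap <- prof$energy[prof$phi == 180] - prof$energy[prof$phi == 0]
  expect_lt(gap, 0)
  expect_equal(gap, -10.19, tolerance = 0.1)
  ## the barrier region stays far above both planar states
  expect_gt(prof$energy[prof$phi == 90] - prof$energy[prof$phi == 0], 50)
})

test_that("dihedral fitting recovers manufactured coefficients exactly", {
  phi <- seq(-180, 170, by = 10)
  ## zero residual -> zero coefficients
  f0 <- fit_dihedral_terms(phi, rep(0, length(phi)), rep(0, length(phi)),
                           list(type = "gromos", m = c(1, 2, 3)))
  expect_equal(f0$terms$k, rep(0, 3), tolerance = 1e-12)

  resid <- 5 * (1 + cos(2 * pi / 180 * phi))
  f1 <- fit_dihedral_terms(phi, resid, rep(0, length(phi)),
                           list(type = "gromos", m = 2))
  expect_equal(f1$terms$k, 5, tolerance = 1e-9)
  expect_equal(f1$offset, 0, tolerance = 1e-9)

  ## RB basis recovery of the HNO2 coefficients from its own curve
  c_true <- get_topology("HNO2")$dihedrals[[1]]$c
  target <- rb_dihedral_energy(phi, c_true)
  f2 <- fit_dihedral_terms(phi, target, rep(0, length(phi)),
                           list(type = "rb", order = 5))
  expect_equal(f2$c, c_true, tolerance = 1e-8)

  ## a one-point grid cannot support the basis
  expect_error(fit_dihedral_terms(c(0, 90), c(0, 0), c(0, 0),
                                  list(type = "rb", order = 5)),
               "rank-deficient")
})

test_that("fitting the HOONO torsional residual recovers the perp minimum", {
  ## manufacture the reference as classical-without-torsion + the bundled
  ## NOOH series; the fit must recover that series and its ~90 degree minimum
  top <- get_topology("HOONO")
  d <- top$dihedrals[[2]]
  phi <- seq(-180, 175, by = 5)
  without <- 0.3 * cos(pi / 180 * phi)   # stand-in background profile
  target <- without + gromos_dihedral_energy(phi, d$terms)
  fit <- fit_dihedral_terms(phi, target, without,
                            list(type = "gromos", m = 1:4))
  expect_equal(fit$terms$k, d$terms$k, tolerance = 1e-9)
  grid <- seq(0, 180, by = 0.5)
  v <- gromos_dihedral_energy(grid, fit$terms)
  expect_equal(grid[which.min(v)], 91, tolerance = 1.5)
})
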
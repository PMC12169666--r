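## Potential-energy terms and whole-molecule evaluation.
##
## GROMOS functional forms: quartic bond stretching 1/4 Kb (b^2 - b0^2)^2,
## cosine-harmonic angle bending 1/2 Kt (cos t - cos t0)^2, harmonic improper
## 1/2 Kx (xi - xi0)^2 (per rad^2), proper dihedral series
## sum K [1 + cos(m phi - phi0)], or the Ryckaert-Bellemans polynomial
## sum Ci cos(phi - 180)^i.  Nonbonded: C12/r^12 - C6/r^6 + f qi qj / r.

#' Quartic bond-stretching energy
#'
#' @param b bond length, nm.
#' @param b0 reference length, nm.
#' @param kb force constant, kJ mol^-1 nm^-4.
#' @param constrained logical; constrained bonds contribute zero energy (their
#'   `kb` is a placeholder and never used).
#' @return Energy in kJ/mol.
#' @export
#' @examples
#' bond_energy(0.11, 0.10, 1e7)
bond_energy <- function(b, b0, kb, constrained = FALSE) {
  if (any(b <= 0) || any(b0 <= 0)) stop("bond lengths must be positive")
  ifelse(rep_len(constrained, length(b)), 0, 0.25 * kb * (b^2 - b0^2)^2)
}

#' Cosine-harmonic angle-bending energy
#'
#' @param theta angle, degrees, in (0, 180].
#' @param theta0 reference angle, degrees.
#' @param k_theta force constant, kJ/mol.
#' @return Energy in kJ/mol.
#' @export
angle_energy <- function(theta, theta0, k_theta) {
  if (any(theta <= 0 | theta > 180)) stop("angle out of range (0, 180]")
  0.5 * k_theta * (cos(.deg2rad(theta)) - cos(.deg2rad(theta0)))^2
}

#' Harmonic improper-dihedral energy
#'
#' The improper angle is measured as the signed out-of-plane dihedral of the
#' listed atom quadruple; the force constant is per rad^2 and the deviation is
#' wrapped into (-180, 180].
#'
#' @param xi improper dihedral angle, degrees.
#' @param xi0 reference, degrees.
#' @param k_xi force constant, kJ mol^-1 rad^-2.
#' @return Energy in kJ/mol.
#' @export
improper_energy <- function(xi, xi0, k_xi) {
  0.5 * k_xi * .deg2rad(.wrap_deg(xi - xi0))^2
}

#' GROMOS proper-dihedral series energy
#'
#' `sum_i K_i [1 + cos(m_i phi - phi0_i)]` over the terms of one dihedral.
#'
#' @param phi dihedral angle, degrees (vectorized).
#' @param terms data frame with columns `m` (multiplicity, >= 1), `phi0`
#'   (phase, degrees, 0 or 180) and `k` (kJ/mol).
#' @return Energy in kJ/mol.
#' @export
#' @examples
#' gromos_dihedral_energy(0, data.frame(m = 2, phi0 = 0, k = -42.3))
gromos_dihedral_energy <- function(phi, terms) {
  if (nrow(terms) == 0) stop("empty dihedral term list")
  if (any(terms$m < 1)) stop("dihedral multiplicity must be >= 1")
  sapply(phi, function(p)
    sum(terms$k * (1 + cos(terms$m * .deg2rad(p) - .deg2rad(terms$phi0)))))
}

#' Ryckaert-Bellemans dihedral energy
#'
#' `sum_{i=0}^{5} C_i [cos(phi - 180)]^i`; the shifted argument makes the
#' trans state (phi = 180) the zero of the cosine polynomial's argument.
#'
#' @param phi dihedral angle, degrees (vectorized).
#' @param c numeric vector of six coefficients C0..C5, kJ/mol.
#' @return Energy in kJ/mol.
#' @export
rb_dihedral_energy <- function(phi, c) {
  stopifnot(length(c) == 6)
  sapply(phi, function(p) sum(c * cos(.deg2rad(p - 180))^(0:5)))
}

#' Pairwise nonbonded energy
#'
#' Lennard-Jones plus Coulomb interaction of one atom pair:
#' `C12/r^12 - C6/r^6 + f qi qj / r`, with the electrostatic prefactor
#' `f = 138.935458 kJ mol^-1 nm e^-2`.
#'
#' @param r interatomic distance, nm (> 0).
#' @param c6,c12 Lennard-Jones coefficients (kJ mol^-1 nm^6 / nm^12).
#' @param qi,qj partial charges, e.
#' @return Energy in kJ/mol.
#' @export
pair_nonbonded_energy <- function(r, c6, c12, qi, qj) {
  if (any(r <= 0)) stop("distance must be positive")
  c12 / r^12 - c6 / r^6 + .CONST$coulomb * qi * qj / r
}

.dihedral_term_energy <- function(d, phi) {
  if (d$type == "gromos") gromos_dihedral_energy(phi, d$terms)
  else rb_dihedral_energy(phi, d$c)
}

#' Evaluate the full intramolecular energy of a conformation
#'
#' Assembles all bonded terms and the nonbonded interactions permitted by the
#' GROMOS exclusion rules: first and second neighbors excluded, third
#' neighbors as explicit 1-4 pairs with modified C12 (full charges) when
#' spanned by a GROMOS dihedral and fully excluded when spanned by an RB
#' dihedral, all remoter pairs at full strength.  Constrained bonds contribute
#' zero.
#'
#' @param topology a `rons_topology`.
#' @param conformation a `rons_conformation` (see [build_conformation()]) or a
#'   plain N x 3 coordinate matrix in nm.
#' @return An object of class `rons_energy`: list with components `bond`,
#'   `angle`, `improper`, `proper_dihedral`, `lj_14`, `coulomb_14`,
#'   `lj_intra`, `coulomb_intra` and `total` (kJ/mol each); `total` is their
#'   sum.
#' @export
#' @examples
#' top <- get_topology("H2O2")
#' conf <- build_conformation(top, reference_internals(top))
#' molecule_energy(top, conf)
molecule_energy <- function(topology, conformation) {
  x <- if (is.matrix(conformation)) conformation else conformation$xyz
  if (nrow(x) != nrow(topology$atoms))
    stop("conformation does not match topology atom count")

  e <- list(bond = 0, angle = 0, improper = 0, proper_dihedral = 0,
            lj_14 = 0, coulomb_14 = 0, lj_intra = 0, coulomb_intra = 0)

  bd <- topology$bonds
  for (b in seq_len(nrow(bd))) {
    r <- sqrt(sum((x[bd$i[b], ] - x[bd$j[b], ])^2))
    e$bond <- e$bond + bond_energy(r, bd$b0[b], bd$kb[b], bd$constrained[b])
  }
  an <- topology$angles
  for (a in seq_len(nrow(an))) {
    th <- measure_angle(x, an$i[a], an$j[a], an$k[a])
    e$angle <- e$angle + angle_energy(th, an$theta0[a], an$k_theta[a])
  }
  im <- topology$impropers
  for (a in seq_len(nrow(im))) {
    xi <- measure_dihedral(x, im$i[a], im$j[a], im$k[a], im$l[a])
    e$improper <- e$improper + improper_energy(xi, im$xi0[a], im$k_xi[a])
  }
  for (d in topology$dihedrals) {
    phi <- measure_dihedral(x, d$i, d$j, d$k, d$l)
    e$proper_dihedral <- e$proper_dihedral + .dihedral_term_energy(d, phi)
  }

  q <- topology$atoms$charge
  p14 <- topology$pairs14
  for (p in seq_len(nrow(p14))) {
    r <- sqrt(sum((x[p14$i[p], ] - x[p14$j[p], ])^2))
    e$lj_14 <- e$lj_14 + p14$c12[p] / r^12 - p14$c6[p] / r^6
    e$coulomb_14 <- e$coulomb_14 +
      .CONST$coulomb * q[p14$i[p]] * q[p14$j[p]] / r
  }

  ## full-range intramolecular pairs: everything not excluded and not 1-4
  n <- nrow(x)
  skip <- new.env(parent = emptyenv())
  mark <- function(d) for (r in seq_len(nrow(d)))
    assign(paste(min(d$i[r], d$j[r]), max(d$i[r], d$j[r])), TRUE, envir = skip)
  mark(topology$exclusions); mark(p14)
  db <- ff_database()
  if (n >= 2) for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (!is.null(skip[[paste(i, j)]])) next
    r <- sqrt(sum((x[i, ] - x[j, ])^2))
    ti <- topology$atoms$type[i]; tj <- topology$atoms$type[j]
    c6 <- combine_c6(ti, tj, db = db)
    c12 <- combine_c12(ti, tj, "normal", db = db)
    e$lj_intra <- e$lj_intra + c12 / r^12 - c6 / r^6
    e$coulomb_intra <- e$coulomb_intra + .CONST$coulomb * q[i] * q[j] / r
  }

  e$total <- e$bond + e$angle + e$improper + e$proper_dihedral +
    e$lj_14 + e$coulomb_14 + e$lj_intra + e$coulomb_intra
  class(e) <- "rons_energy"
  e
}

#' @export
print.rons_energy <- function(x, ...) {
  comp <- unlist(x[setdiff(names(x), "total")])
  for (nm in names(comp)) cat(sprintf("  %-16s %12.6f kJ/mol\n", nm, comp[nm]))
  cat(sprintf("  %-16s %12.6f kJ/mol\n", "total", x$total))
  invisible(x)
}
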
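## Thermodynamic post-processing: TI quadrature, heat of vaporization,
## torsional isomerization free energy and the two-conformer weighted
## hydration free energy.

#' Construct a thermodynamic-integration dataset
#'
#' Holds the ensemble-averaged Hamiltonian derivatives of the two decoupling
#' legs (Coulomb first, then Lennard-Jones) on their lambda grids.
#'
#' @param coulomb_leg,lj_leg data frames (or two-column matrices) with
#'   columns `lambda` (in \[0, 1\], strictly increasing, endpoints present)
#'   and `dhdl` (kJ/mol).
#' @param solute,solvent,temperature optional metadata.
#' @return An object of class `rons_ti`.
#' @export
ti_dataset <- function(coulomb_leg, lj_leg, solute = NA, solvent = NA,
                       temperature = 298) {
  tidy <- function(leg, name) {
    leg <- as.data.frame(leg)
    names(leg)[1:2] <- c("lambda", "dhdl")
    if (any(leg$lambda < 0 | leg$lambda > 1))
      stop(name, ": lambda out of [0, 1]")
    if (any(diff(leg$lambda) <= 0))
      stop(name, ": lambda grid must be strictly increasing")
    if (leg$lambda[1] != 0 || leg$lambda[nrow(leg)] != 1)
      stop(name, ": lambda endpoints 0 and 1 required")
    leg
  }
  structure(list(coulomb_leg = tidy(coulomb_leg, "coulomb_leg"),
                 lj_leg = tidy(lj_leg, "lj_leg"),
                 solute = solute, solvent = solvent,
                 temperature = temperature),
            class = "rons_ti")
}

#' Read one TI leg from a two-column text file
#'
#' Plain whitespace-separated text, two columns (lambda, <dH/dlambda>);
#' lines starting with `#`, `@` or `;` are ignored.
#'
#' @param path file path.
#' @return Data frame with columns `lambda` and `dhdl`.
#' @export
read_ti_leg <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*([#@;]|$)", lines)]
  d <- utils::read.table(text = lines)
  stats::setNames(d[, 1:2], c("lambda", "dhdl"))
}

#' Integrate a TI dataset into a solvation free energy
#'
#' Composite quadrature of each decoupling leg on its own lambda grid,
#' composed as `dG_solv = -(I_coulomb + I_lj)`; the per-leg contributions are
#' reported with the same sign convention, so `dG_total = dG_coulomb +
#' dG_lj` exactly.
#'
#' @param dataset a `rons_ti` (see [ti_dataset()]).
#' @param method `"trapezoid"` (default, grid-faithful) or `"simpson"`
#'   (requires an odd number of uniformly spaced points per leg).
#' @return An object of class `rons_solvation`: list with `dG_total`,
#'   `dG_coulomb`, `dG_lj` (kJ/mol).
#' @export
#' @examples
#' coul <- data.frame(lambda = seq(0, 1, 0.05), dhdl = -10)
#' lj   <- data.frame(lambda = seq(0, 1, 0.02), dhdl = -10)
#' ti_integrate(ti_dataset(coul, lj))  # dG = +20
ti_integrate <- function(dataset, method = c("trapezoid", "simpson")) {
  method <- match.arg(method)
  quad <- function(leg) {
    if (method == "trapezoid") {
      pracma::trapz(leg$lambda, leg$dhdl)
    } else {
      n <- nrow(leg)
      h <- diff(leg$lambda)
      if (n < 3 || n %% 2 == 0 || any(abs(h - h[1]) > 1e-12))
        stop("Simpson quadrature needs an odd number of uniform points")
      h <- h[1]
      ## composite Simpson weights 1,4,2,...,2,4,1
      w <- rep(2, n); w[seq(2, n - 1, by = 2)] <- 4; w[c(1, n)] <- 1
      h / 3 * sum(w * leg$dhdl)
    }
  }
  dGc <- -quad(dataset$coulomb_leg)
  dGl <- -quad(dataset$lj_leg)
  structure(list(dG_total = dGc + dGl, dG_coulomb = dGc, dG_lj = dGl),
            class = "rons_solvation")
}

#' @export
print.rons_solvation <- function(x, ...) {
  cat(sprintf("dG_solv = %.3f kJ/mol (Coulomb %.3f, LJ %.3f)\n",
              x$dG_total, x$dG_coulomb, x$dG_lj))
  invisible(x)
}

#' Heat of vaporization
#'
#' `dHvap = U_gas - U_liq + R T` from the mean intramolecular-plus-
#' intermolecular potential energies per mole of the gas and liquid phases.
#'
#' @param u_gas,u_liq mean potential energies, kJ/mol.
#' @param T absolute temperature, K.
#' @return dHvap in kJ/mol.
#' @export
#' @examples
#' heat_of_vaporization(0, 0, 298.15)  # RT
heat_of_vaporization <- function(u_gas, u_liq, T = 298) {
  if (any(T <= 0)) stop("temperature must be positive")
  u_gas - u_liq + .CONST$R * T
}

.torsion_potential_fun <- function(terms) {
  if (is.data.frame(terms)) {
    function(phi) gromos_dihedral_energy(phi, terms)
  } else if (is.numeric(terms) && length(terms) == 6) {
    function(phi) rb_dihedral_energy(phi, terms)
  } else if (inherits(terms, "rons_topology")) {
    d <- terms$dihedrals
    if (length(d) != 1)
      stop("topology must carry exactly one proper dihedral; pass the term directly")
    function(phi) .dihedral_term_energy(d[[1]], phi)
  } else stop("terms must be a GROMOS term data frame, six RB coefficients, ",
              "or a single-dihedral topology")
}

#' Gas-phase trans-to-cis torsional isomerization free energy
#'
#' Derived from a one-dimensional torsional potential with a cis-type basin
#' (|phi| < 90) and a trans-type basin (|phi| >= 90).  `mode = "minima"`
#' returns V(cis minimum) - V(trans minimum); `mode = "boltzmann"` returns
#' `-RT ln(Z_cis / Z_trans)` with Z the Boltzmann integral of the bare
#' torsional potential over each half-range.
#'
#' @param terms the torsional potential: a GROMOS term data frame
#'   (`m`, `phi0`, `k`), six RB coefficients, or a topology with a single
#'   proper dihedral.
#' @param mode `"minima"` (default) or `"boltzmann"`.
#' @param T temperature, K (used by the Boltzmann mode).
#' @return dG_i (trans -> cis), kJ/mol.
#' @export
#' @examples
#' torsional_isomerization_dG(get_topology("HNO2")$dihedrals[[1]]$c)
torsional_isomerization_dG <- function(terms, mode = c("minima", "boltzmann"),
                                       T = 298) {
  mode <- match.arg(mode)
  V <- .torsion_potential_fun(terms)
  phi <- seq(-180, 180, by = 0.05)
  v <- V(phi)
  cis <- abs(phi) < 90
  vmin_cis <- min(v[cis]); vmin_trans <- min(v[!cis])
  ## the basin boundary (phi = +-90) must lie above both basin minima,
  ## otherwise the potential has a single basin and dGi is undefined
  vboundary <- min(V(90), V(-90))
  if (vboundary <= max(vmin_cis, vmin_trans) + 1e-9)
    stop("potential has a single basin; isomerization undefined")
  if (mode == "minima") {
    vmin_cis - vmin_trans
  } else {
    RT <- .CONST$R * T
    vref <- min(v)
    z_cis <- pracma::trapz(phi[cis], exp(-(v[cis] - vref) / RT))
    z_trans <- pracma::trapz(phi[!cis & phi > 0], exp(-(v[!cis & phi > 0] - vref) / RT)) +
      pracma::trapz(phi[!cis & phi < 0], exp(-(v[!cis & phi < 0] - vref) / RT))
    -RT * log(z_cis / z_trans)
  }
}

#' Two-conformer weighted hydration free energy
#'
#' Thermodynamic-cycle combination of conformer-specific hydration free
#' energies with the gas-phase trans-to-cis isomerization free energy:
#' \deqn{\Delta G_w = \Delta G_{w,trans} - RT \ln
#'   \frac{1 + e^{(-\Delta G_i + \Delta G_{w,trans} - \Delta G_{w,cis})/RT}}
#'        {1 + e^{-\Delta G_i/RT}}}
#'
#' @param dGw_trans,dGw_cis conformer hydration free energies, kJ/mol.
#' @param dGi gas-phase trans-to-cis isomerization free energy, kJ/mol.
#' @param T temperature, K (> 0).
#' @return Weighted hydration free energy, kJ/mol.
#' @export
#' @examples
#' conformer_weighted_dGw(-18.0, -11.2, 1.556, T = 298)
conformer_weighted_dGw <- function(dGw_trans, dGw_cis, dGi, T = 298) {
  if (T <= 0) stop("temperature must be positive")
  RT <- .CONST$R * T
  dGw_trans - RT * log((1 + exp((-dGi + dGw_trans - dGw_cis) / RT)) /
                         (1 + exp(-dGi / RT)))
}
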
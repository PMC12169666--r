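## Rigid-bond minimization, conformer tables, torsional scans and
## dihedral-term fitting.

## Map a requested dihedral quadruple onto a Z-matrix placement variable.
.match_placement_dihedral <- function(zm, quad) {
  for (rix in seq_len(nrow(zm))) {
    r <- zm[rix, ]
    if (is.na(r$dihedral_var)) next
    pq <- c(r$l, r$i, r$j, r$atom)
    if (all(pq == quad) || all(pq == rev(quad))) return(r$dihedral_var)
  }
  NULL
}

.objective_factory <- function(topology, zm, start_int, free, restraints) {
  var_names <- names(start_int)
  function(p_deg) {
    full <- start_int
    full[free] <- p_deg
    conf <- build_conformation(topology, full)
    e <- molecule_energy(topology, conf)$total
    if (!is.null(restraints)) for (r in restraints) {
      phi <- measure_dihedral(conf$xyz, r$quad[1], r$quad[2], r$quad[3], r$quad[4])
      e <- e + 0.5 * r$k * .deg2rad(.wrap_deg(phi - r$target))^2
    }
    e
  }
}

#' Minimize a molecule's energy with rigid bonds
#'
#' Local minimization of [molecule_energy()] over the internal-coordinate
#' manifold with every bond fixed at its reference length b0: the free
#' variables are the Z-matrix placement angles and dihedrals (see
#' [build_zmatrix()]).  Deterministic quasi-Newton (BFGS) with a fixed start;
#' selected dihedrals can be pinned exactly (removed from the variable set)
#' or restrained harmonically.
#'
#' @param topology a `rons_topology`.
#' @param start a `rons_conformation`, coordinate matrix, or named internal
#'   vector as accepted by [build_conformation()].
#' @param restraints optional list of harmonic dihedral restraints, each a
#'   list `(quad = c(i,j,k,l), target = degrees, k = kJ mol^-1 rad^-2)`.
#' @param pin_dihedrals optional list of dihedral quadruples (or Z-matrix
#'   `dih_*` labels) held exactly fixed at their start values.
#' @param maxit iteration cap (default 1e4).
#' @param grad_tol convergence threshold on the gradient norm, kJ/mol per
#'   degree.
#' @return An object of class `rons_conformer`: list with `conformation`,
#'   `energy` (kJ/mol), `internals` (placement variables at the minimum),
#'   `angles` and `dihedrals` (measured force-field internals, degrees),
#'   `converged`, `grad_norm` and `pinned`.  Non-convergence within the
#'   iteration budget is flagged, never silent.
#' @export
#' @examples
#' top <- get_topology("H2O2")
#' res <- minimize_rigid_bonds(top, reference_internals(top, dihedrals = 60))
#' res$dihedrals  # HOOH settles at its skewed equilibrium
minimize_rigid_bonds <- function(topology, start, restraints = NULL,
                                 pin_dihedrals = NULL, maxit = 10000,
                                 grad_tol = 1e-6) {
  zm <- build_zmatrix(topology)
  start_int <- if (is.numeric(start) && !is.null(names(start))) start
    else measure_internals(topology, start)

  pinned <- character()
  if (!is.null(pin_dihedrals)) for (p in pin_dihedrals) {
    v <- if (is.character(p)) p else .match_placement_dihedral(zm, p)
    if (is.null(v) || !(v %in% names(start_int)))
      stop("pinned dihedral is not a placement variable of this topology; ",
           "use a harmonic restraint instead", call. = FALSE)
    pinned <- c(pinned, v)
  }
  free <- setdiff(names(start_int), pinned)
  fobj <- .objective_factory(topology, zm, start_int, free, restraints)

  full <- start_int
  grad_norm <- NA_real_
  if (length(free) > 0) {
    par <- start_int[free]
    value <- fobj(par)
    for (round in 1:6) {
      o <- stats::optim(par, fobj, method = "BFGS",
                        control = list(maxit = maxit, reltol = 1e-15))
      par <- o$par
      g <- pracma::grad(fobj, par, heps = 1e-5)
      grad_norm <- sqrt(sum(g^2))
      improved <- o$value < value - 1e-13
      value <- o$value
      if (grad_norm < grad_tol || !improved) break
    }
    full[free] <- par
  } else {
    grad_norm <- 0
  }

  conf <- build_conformation(topology, full)
  energy <- molecule_energy(topology, conf)$total
  an <- topology$angles
  meas_ang <- if (nrow(an) > 0)
    stats::setNames(mapply(function(i, j, k) measure_angle(conf$xyz, i, j, k),
                           an$i, an$j, an$k),
                    sprintf("ang_%d_%d_%d", an$i, an$j, an$k))
  else numeric(0)
  meas_dih <- if (length(topology$dihedrals) > 0)
    stats::setNames(vapply(topology$dihedrals, function(d)
      measure_dihedral(conf$xyz, d$i, d$j, d$k, d$l), 0),
      vapply(topology$dihedrals, function(d) d$label, ""))
  else numeric(0)

  structure(list(
    species = topology$species,
    conformation = conf, energy = energy, internals = full,
    angles = meas_ang, dihedrals = meas_dih,
    converged = is.na(grad_norm) || grad_norm < grad_tol,
    grad_norm = grad_norm, pinned = pinned
  ), class = "rons_conformer")
}

#' @export
print.rons_conformer <- function(x, ...) {
  cat(sprintf("%s minimized: E = %.4f kJ/mol (%s, |grad| = %.2e kJ/mol/deg)\n",
              x$species, x$energy,
              if (x$converged) "converged" else "NOT CONVERGED", x$grad_norm))
  if (length(x$dihedrals) > 0) {
    cat("  dihedrals: ",
        paste(sprintf("%s = %.1f", names(x$dihedrals), x$dihedrals),
              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Minimize a set of conformers and tabulate relative energies
#'
#' Runs [minimize_rigid_bonds()] for each conformer specification and reports
#' energies relative to the first entry.  A free (unpinned) minimization
#' whose dihedrals drift more than 30 degrees from the start is flagged as a
#' basin escape.
#'
#' @param topology a `rons_topology`.
#' @param specs list of conformer specifications: each a list with `label`,
#'   `internal` (named start vector for [build_conformation()]) and optional
#'   `pin_dihedrals` (as in [minimize_rigid_bonds()]).
#' @return Data frame of class `rons_conformer_table` with one row per
#'   conformer (`label`, `energy`, `delta_e`, measured force-field angle and
#'   dihedral columns, `converged`, `basin_escape`, `pinned`), plus the full
#'   results in `attr(, "results")`.
#' @export
#' @examples
#' top <- get_topology("HOONO")
#' tab <- conformer_table(top, hoono_conformer_specs(top))
#' tab[, c("label", "delta_e", "ONOO", "NOOH")]
conformer_table <- function(topology, specs) {
  results <- lapply(specs, function(sp) {
    res <- minimize_rigid_bonds(topology, sp$internal,
                                pin_dihedrals = sp$pin_dihedrals)
    start_dih <- sp$internal[grep("^dih_", names(sp$internal))]
    drift <- abs(.wrap_deg(res$internals[names(start_dih)] - start_dih))
    res$basin_escape <- length(sp$pin_dihedrals) == 0 && any(drift > 30)
    res$label <- sp$label
    res
  })
  e0 <- results[[1]]$energy
  tab <- do.call(rbind, lapply(results, function(r) {
    row <- data.frame(label = r$label, energy = r$energy,
                      delta_e = r$energy - e0,
                      converged = r$converged,
                      basin_escape = r$basin_escape,
                      pinned = length(r$pinned) > 0,
                      stringsAsFactors = FALSE)
    for (nm in names(r$dihedrals)) row[[nm]] <- r$dihedrals[nm]
    row
  }))
  attr(tab, "results") <- results
  class(tab) <- c("rons_conformer_table", class(tab))
  tab
}

#' Bundled HOONO conformer specifications
#'
#' The eight HOONO conformers with their quantum-reference start internals.
#' cis-gauche (no classical stationary point of its own) is pinned at the
#' quantum-reference dihedrals; perp-perp is pinned at the classical
#' stationary region of the O-N-O-O barrier.  All others minimize freely.
#'
#' @param topology the HOONO topology (defaults to the bundled one).
#' @return List of conformer specifications for [conformer_table()].
#' @export
hoono_conformer_specs <- function(topology = get_topology("HOONO")) {
  path <- system.file("extdata", "gromos_rons", "conformers_hoono.tsv",
                      package = "ronsff", mustWork = TRUE)
  tb <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  lapply(seq_len(nrow(tb)), function(r) {
    row <- tb[r, ]
    internal <- c(ang_3_2_1 = row$ONO, ang_4_3_2 = row$NOO, ang_5_4_3 = row$OOH,
                  dih_1_2_3_4 = row$ONOO, dih_2_3_4_5 = row$NOOH)
    pins <- list()
    if (isTRUE(row$pin_onoo)) pins <- c(pins, list(c(1, 2, 3, 4)))
    if (isTRUE(row$pin_nooh)) pins <- c(pins, list(c(2, 3, 4, 5)))
    list(label = row$label, internal = internal, pin_dihedrals = pins)
  })
}

#' Scan a torsional profile
#'
#' Either evaluates the bare dihedral potential of one torsion on a grid
#' (`mode = "torsion_only"`), or pins the torsion at each grid value and
#' relaxes all remaining internals with bonds rigid
#' (`mode = "full_molecule_relaxed"`; energies are totals, with continuation
#' between grid points).
#'
#' @param topology a `rons_topology`.
#' @param dihedral atom quadruple `c(i, j, k, l)` of a dihedral carrying a
#'   potential in the topology.
#' @param grid numeric vector of dihedral values, degrees, strictly
#'   increasing within (-180, 180].
#' @param mode `"torsion_only"` or `"full_molecule_relaxed"`.
#' @param start optional start internals for the relaxed mode (default:
#'   [reference_internals()]).
#' @return Data frame of class `rons_torsion_profile` with columns `phi`,
#'   `energy` and (relaxed mode) `converged`.
#' @export
#' @examples
#' top <- get_topology("ONOO-")
#' prof <- torsion_scan(top, c(1, 2, 3, 4), seq(-180, 180, by = 5))
torsion_scan <- function(topology, dihedral, grid,
                         mode = c("torsion_only", "full_molecule_relaxed"),
                         start = NULL) {
  mode <- match.arg(mode)
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  term <- NULL
  for (d in topology$dihedrals) {
    quad <- c(d$i, d$j, d$k, d$l)
    if (all(quad == dihedral) || all(quad == rev(dihedral))) term <- d
  }
  if (is.null(term))
    stop("no dihedral potential on atoms ", paste(dihedral, collapse = "-"))

  if (mode == "torsion_only") {
    e <- .dihedral_term_energy(term, grid)
    out <- data.frame(phi = grid, energy = e)
  } else {
    zm <- build_zmatrix(topology)
    var <- .match_placement_dihedral(zm, dihedral)
    if (is.null(var))
      stop("dihedral is not a placement variable; cannot pin for relaxation")
    internal <- if (is.null(start)) reference_internals(topology) else start
    e <- numeric(length(grid)); conv <- logical(length(grid))
    for (gix in seq_along(grid)) {
      internal[var] <- grid[gix]
      res <- minimize_rigid_bonds(topology, internal, pin_dihedrals = list(var))
      e[gix] <- res$energy; conv[gix] <- res$converged
      internal <- res$internals   # continuation
    }
    out <- data.frame(phi = grid, energy = e, converged = conv)
  }
  attr(out, "mode") <- mode
  attr(out, "dihedral") <- dihedral
  class(out) <- c("rons_torsion_profile", class(out))
  out
}

#' Fit dihedral-series coefficients to a residual profile
#'
#' Implements the classical dihedral-calibration step: the target (reference)
#' profile minus the classical profile evaluated without the torsional term
#' defines a residual, which is fitted by linear least squares in either a
#' GROMOS cosine series or a Ryckaert-Bellemans polynomial.  Any constant
#' offset is absorbed (reported separately for the GROMOS basis, folded into
#' C0 for the RB basis).
#'
#' @param phi grid of dihedral values, degrees.
#' @param target reference energies on `phi`, kJ/mol.
#' @param classical_without_torsion classical energies on `phi` with the
#'   torsional term removed, kJ/mol.
#' @param basis either `list(type = "gromos", m = <multiplicities>, phi0 = 0)`
#'   or `list(type = "rb", order = 5)`.
#' @return For the GROMOS basis: list with `terms` (data frame `m`, `phi0`,
#'   `k`), `offset` and `rmsd`.  For the RB basis: list with `c`
#'   (coefficients C0..C_order, trailing zeros to six) and `rmsd`.
#' @export
#' @examples
#' phi <- seq(-180, 170, by = 10)
#' resid <- 5 * (1 + cos(2 * pi * phi / 180))
#' fit_dihedral_terms(phi, resid, 0 * phi, list(type = "gromos", m = 2))
fit_dihedral_terms <- function(phi, target, classical_without_torsion, basis) {
  resid <- target - classical_without_torsion
  if (basis$type == "gromos") {
    m <- basis$m
    phi0 <- if (is.null(basis$phi0)) rep(0, length(m)) else
      rep_len(basis$phi0, length(m))
    if (!all(phi0 %in% c(0, 180))) stop("phi0 must be 0 or 180")
    sgn <- ifelse(phi0 == 0, 1, -1)
    X <- sapply(seq_along(m), function(t)
      sgn[t] * cos(m[t] * .deg2rad(phi)))
    X <- cbind(X)
    colnames(X) <- sprintf("cos%d", m)
    qrX <- qr(cbind(1, X))
    if (qrX$rank < ncol(X) + 1)
      stop("rank-deficient basis for the given grid")
    fit <- stats::lm.fit(cbind(intercept = 1, X), resid)
    k <- unname(fit$coefficients[-1])
    offset <- unname(fit$coefficients[1]) - sum(k)
    pred <- drop(cbind(1, X) %*% fit$coefficients)
    list(terms = data.frame(m = m, phi0 = phi0, k = k),
         offset = offset,
         rmsd = sqrt(mean((resid - pred)^2)))
  } else if (basis$type == "rb") {
    order <- if (is.null(basis$order)) 5 else basis$order
    psi <- cos(.deg2rad(phi - 180))
    X <- sapply(1:order, function(i) psi^i)
    qrX <- qr(cbind(1, X))
    if (qrX$rank < order + 1)
      stop("rank-deficient basis for the given grid")
    fit <- stats::lm.fit(cbind(1, X), resid)
    cc <- unname(fit$coefficients)
    pred <- drop(cbind(1, X) %*% fit$coefficients)
    list(c = c(cc, rep(0, 6 - length(cc)))[1:6],
         rmsd = sqrt(mean((resid - pred)^2)))
  } else stop("unknown basis type: ", basis$type)
}
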
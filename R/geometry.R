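## Rigid-bond geometry engine: internal-coordinate (Z-matrix) construction
## over the spanning bond tree, Cartesian building via the natural-extension
## reference frame, and angle/dihedral measurement.

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Measure a bond angle
#'
#' @param x N x 3 coordinate matrix (nm) or `rons_conformation`.
#' @param i,j,k atom indices; the angle is at `j`.
#' @return Angle in degrees, in \[0, 180\].
#' @export
measure_angle <- function(x, i, j, k) {
  if (!is.matrix(x)) x <- x$xyz
  v1 <- x[i, ] - x[j, ]; v2 <- x[k, ] - x[j, ]
  cs <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  .rad2deg(acos(pmin(1, pmax(-1, cs))))
}

#' Measure a signed dihedral angle
#'
#' Standard IUPAC convention: phi = 0 for the cis (eclipsed) arrangement of
#' `i` and `l` about the `j`-`k` axis, positive for clockwise rotation viewed
#' from `j` towards `k`; range (-180, 180].
#'
#' @param x N x 3 coordinate matrix (nm) or `rons_conformation`.
#' @param i,j,k,l four distinct atom indices.
#' @return Signed dihedral in degrees.
#' @export
#' @examples
#' x <- rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))
#' measure_dihedral(x, 1, 2, 3, 4)  # planar cis: 0
measure_dihedral <- function(x, i, j, k, l) {
  if (!is.matrix(x)) x <- x$xyz
  if (length(unique(c(i, j, k, l))) != 4) stop("atoms must be distinct")
  b1 <- x[j, ] - x[i, ]; b2 <- x[k, ] - x[j, ]; b3 <- x[l, ] - x[k, ]
  n1 <- .cross3(b1, b2); n2 <- .cross3(b2, b3)
  if (sum(n1^2) < 1e-20 || sum(n2^2) < 1e-20)
    stop("collinear atoms: dihedral undefined")
  phi <- atan2(sqrt(sum(b2^2)) * sum(b1 * n2), sum(n1 * n2))
  .rad2deg(phi)
}

#' Z-matrix placement table of a topology
#'
#' Derives a deterministic internal-coordinate parameterization from the
#' bonded graph: atoms are placed in breadth-first order from atom 1 along
#' the (acyclic) bond tree; each atom after the third is placed by a bond
#' length (fixed at b0), a placement angle and a placement dihedral.  The
#' free variables of the rigid-bond manifold are exactly the placement angles
#' and dihedrals.
#'
#' @param topology a `rons_topology`.
#' @return Data frame with one row per placed atom: `atom`, reference atoms
#'   `j` (bonded parent), `i` (angle reference), `l` (dihedral reference),
#'   `b0`, and the variable labels `angle_var`/`dihedral_var` (`NA` where a
#'   reference does not apply).  Placement quadruples are reported in
#'   measurement order (`l`, `i`, `j`, `atom`).
#' @export
build_zmatrix <- function(topology) {
  n <- nrow(topology$atoms)
  bonds <- topology$bonds
  adj <- vector("list", n)
  blen <- new.env(parent = emptyenv())
  for (b in seq_len(nrow(bonds))) {
    i <- bonds$i[b]; j <- bonds$j[b]
    adj[[i]] <- sort(c(adj[[i]], j))
    adj[[j]] <- sort(c(adj[[j]], i))
    assign(paste(min(i, j), max(i, j)), bonds$b0[b], envir = blen)
  }
  order <- 1L; parent <- rep(NA_integer_, n)
  queue <- 1L; seen <- rep(FALSE, n); seen[1] <- TRUE
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) if (!seen[w]) {
      seen[w] <- TRUE; parent[w] <- v
      order <- c(order, w); queue <- c(queue, w)
    }
  }
  if (length(order) != n) stop("bond graph is disconnected")

  placed <- integer()
  rows <- list()
  for (a in order) {
    j <- parent[a]
    i <- l <- NA_integer_
    if (!is.na(j)) {
      cand_i <- c(parent[j], setdiff(intersect(adj[[j]], placed), a))
      cand_i <- cand_i[!is.na(cand_i)]
      if (length(cand_i) > 0) i <- cand_i[1]
    }
    if (!is.na(i)) {
      cand_l <- c(parent[i], setdiff(intersect(adj[[i]], placed), c(a, j)),
                  setdiff(intersect(adj[[j]], placed), c(a, i)))
      cand_l <- unique(cand_l[!is.na(cand_l)])
      cand_l <- setdiff(cand_l, c(a, i, j))
      if (length(cand_l) > 0) l <- cand_l[1]
    }
    rows[[length(rows) + 1]] <- data.frame(
      atom = a, j = j, i = i, l = l,
      b0 = if (is.na(j)) NA_real_ else
        get(paste(min(a, j), max(a, j)), envir = blen),
      angle_var = if (is.na(i)) NA_character_ else
        sprintf("ang_%d_%d_%d", a, j, i),
      dihedral_var = if (is.na(l)) NA_character_ else
        sprintf("dih_%d_%d_%d_%d", l, i, j, a),
      stringsAsFactors = FALSE)
    placed <- c(placed, a)
  }
  do.call(rbind, rows)
}

#' Build Cartesian coordinates from internal coordinates
#'
#' Places atoms sequentially by the natural-extension reference frame: the
#' first atom at the origin, the second along +x, the third in the xy plane,
#' and every further atom from its bond length, placement angle and placement
#' dihedral.  Measured internals of the result reproduce the inputs to
#' numerical precision.
#'
#' @param topology a `rons_topology`.
#' @param internal named numeric vector of placement variables (degrees), with
#'   names as produced by [build_zmatrix()] (`ang_*`, `dih_*`); bond lengths
#'   are taken from the topology's b0 values unless overridden by entries
#'   named `b_<i>_<j>`.
#' @return A `rons_conformation`: list with `species` and the N x 3 `xyz`
#'   matrix (nm).
#' @export
#' @examples
#' top <- get_topology("H2O2")
#' conf <- build_conformation(top, reference_internals(top))
#' measure_dihedral(conf, 1, 2, 3, 4)
build_conformation <- function(topology, internal) {
  zm <- build_zmatrix(topology)
  n <- nrow(zm)
  x <- matrix(NA_real_, nrow(topology$atoms), 3)
  getvar <- function(nm) {
    if (!nm %in% names(internal))
      stop("missing internal coordinate: ", nm, call. = FALSE)
    unname(internal[nm])
  }
  blen <- function(r) {
    nm <- sprintf("b_%d_%d", min(r$atom, r$j), max(r$atom, r$j))
    if (nm %in% names(internal)) unname(internal[nm]) else r$b0
  }
  for (rix in seq_len(n)) {
    r <- zm[rix, ]
    a <- r$atom
    if (is.na(r$j)) {
      x[a, ] <- c(0, 0, 0)
    } else if (is.na(r$i)) {
      x[a, ] <- x[r$j, ] + c(blen(r), 0, 0)
    } else if (is.na(r$l)) {
      th <- .deg2rad(getvar(r$angle_var))
      if (th <= 0 || th >= pi)
        stop("degenerate placement angle for atom ", a, call. = FALSE)
      dirn <- x[r$j, ] - x[r$i, ]
      dirn <- dirn / sqrt(sum(dirn^2))
      ## rotate within the xy plane
      perp <- c(-dirn[2], dirn[1], 0)
      if (sum(perp^2) < 1e-20) perp <- c(0, 1, 0)
      perp <- perp / sqrt(sum(perp^2))
      ## along -dirn (away from the angle reference) rotated by th
      x[a, ] <- x[r$j, ] + blen(r) * (-cos(th) * dirn + sin(th) * perp)
    } else {
      th <- .deg2rad(getvar(r$angle_var))
      if (th <= 0 || th >= pi)
        stop("degenerate placement angle for atom ", a, call. = FALSE)
      ph <- .deg2rad(getvar(r$dihedral_var))
      xi <- x[r$l, ]; xj <- x[r$i, ]; xk <- x[r$j, ]
      bc <- xk - xj; bc <- bc / sqrt(sum(bc^2))
      ab <- xj - xi
      nrm <- .cross3(ab, bc)
      if (sum(nrm^2) < 1e-16)
        stop("collinear placement references for atom ", a, call. = FALSE)
      nrm <- nrm / sqrt(sum(nrm^2))
      m <- .cross3(nrm, bc)
      d2 <- c(-blen(r) * cos(th), blen(r) * sin(th) * cos(ph),
              blen(r) * sin(th) * sin(ph))
      x[a, ] <- xk + d2[1] * bc + d2[2] * m + d2[3] * nrm
    }
  }
  structure(list(species = topology$species, xyz = x),
            class = "rons_conformation")
}

#' Measure the placement internals of a conformation
#'
#' Inverse of [build_conformation()]: measures every placement angle and
#' dihedral of the topology's Z-matrix on the given coordinates.
#'
#' @param topology a `rons_topology`.
#' @param conformation coordinates (matrix or `rons_conformation`).
#' @return Named numeric vector (degrees) of `ang_*` and `dih_*` variables.
#' @export
measure_internals <- function(topology, conformation) {
  x <- if (is.matrix(conformation)) conformation else conformation$xyz
  zm <- build_zmatrix(topology)
  out <- numeric(0)
  for (rix in seq_len(nrow(zm))) {
    r <- zm[rix, ]
    if (!is.na(r$angle_var))
      out[r$angle_var] <- measure_angle(x, r$atom, r$j, r$i)
    if (!is.na(r$dihedral_var))
      out[r$dihedral_var] <- measure_dihedral(x, r$l, r$i, r$j, r$atom)
  }
  out
}

#' Reference internal coordinates of a topology
#'
#' Convenience start: every placement angle at the force-field reference
#' theta0 of the matching angle term (or 109.5 degrees when no term covers
#' it) and every placement dihedral at a supplied value (default 0).
#'
#' @param topology a `rons_topology`.
#' @param dihedrals named numeric vector (by `dih_*` label) or single default
#'   value for all placement dihedrals, degrees.
#' @return Named numeric vector suitable for [build_conformation()].
#' @export
reference_internals <- function(topology, dihedrals = 0) {
  zm <- build_zmatrix(topology)
  an <- topology$angles
  out <- numeric(0)
  for (rix in seq_len(nrow(zm))) {
    r <- zm[rix, ]
    if (!is.na(r$angle_var)) {
      th <- 109.5
      for (a in seq_len(nrow(an))) {
        trip <- c(an$i[a], an$j[a], an$k[a])
        if (an$j[a] == r$j && setequal(c(trip[1], trip[3]), c(r$atom, r$i)))
          th <- an$theta0[a]
      }
      out[r$angle_var] <- th
    }
    if (!is.na(r$dihedral_var)) {
      out[r$dihedral_var] <- if (length(dihedrals) == 1 && is.null(names(dihedrals)))
        dihedrals
      else if (r$dihedral_var %in% names(dihedrals))
        unname(dihedrals[r$dihedral_var])
      else 0
    }
  }
  out
}
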
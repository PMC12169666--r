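# Independent brute-force energy oracle.
#
# Re-derives everything from the topology's raw term lists and the atom-type
# tables: graph distances by adjacency-matrix powers (not BFS), dihedrals via
# projection onto the plane normal (not atan2 of cross products), pair terms
# by explicit enumeration of all atom pairs with the exclusion rules applied
# from scratch.  Shares only the parameter *data* with the implementation.

oracle_dihedral <- function(x, i, j, k, l) {
  b <- x[k, ] - x[j, ]
  b <- b / sqrt(sum(b^2))
  u <- (x[i, ] - x[j, ]); u <- u - sum(u * b) * b
  w <- (x[l, ] - x[k, ]); w <- w - sum(w * b) * b
  cosphi <- sum(u * w) / sqrt(sum(u^2) * sum(w^2))
  phi <- acos(pmin(1, pmax(-1, cosphi))) * 180 / pi
  ## sign: positive if w is clockwise from u looking down j -> k
  s <- sum(b * c(u[2] * w[3] - u[3] * w[2],
                 u[3] * w[1] - u[1] * w[3],
                 u[1] * w[2] - u[2] * w[1]))
  if (s < 0) -phi else phi
}

oracle_energy <- function(top, xyz, db = ff_database()) {
  d2r <- pi / 180
  n <- nrow(top$atoms)
  e <- 0
  ## bonded terms
  for (b in seq_len(nrow(top$bonds))) {
    if (!top$bonds$constrained[b]) {
      r <- sqrt(sum((xyz[top$bonds$i[b], ] - xyz[top$bonds$j[b], ])^2))
      e <- e + 0.25 * top$bonds$kb[b] * (r^2 - top$bonds$b0[b]^2)^2
    }
  }
  for (a in seq_len(nrow(top$angles))) {
    v1 <- xyz[top$angles$i[a], ] - xyz[top$angles$j[a], ]
    v2 <- xyz[top$angles$k[a], ] - xyz[top$angles$j[a], ]
    ct <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
    e <- e + 0.5 * top$angles$k_theta[a] * (ct - cos(top$angles$theta0[a] * d2r))^2
  }
  for (a in seq_len(nrow(top$impropers))) {
    xi <- oracle_dihedral(xyz, top$impropers$i[a], top$impropers$j[a],
                          top$impropers$k[a], top$impropers$l[a])
    dxi <- (xi - top$impropers$xi0[a] + 180) %% 360 - 180
    e <- e + 0.5 * top$impropers$k_xi[a] * (dxi * d2r)^2
  }
  for (d in top$dihedrals) {
    phi <- oracle_dihedral(xyz, d$i, d$j, d$k, d$l)
    if (d$type == "gromos") {
      e <- e + sum(d$terms$k * (1 + cos(d$terms$m * phi * d2r -
                                          d$terms$phi0 * d2r)))
    } else {
      e <- e + sum(d$c * cos((phi - 180) * d2r)^(0:5))
    }
  }
  ## nonbonded: enumerate all pairs, derive exclusions from scratch
  A <- matrix(0, n, n)
  for (b in seq_len(nrow(top$bonds))) {
    A[top$bonds$i[b], top$bonds$j[b]] <- 1
    A[top$bonds$j[b], top$bonds$i[b]] <- 1
  }
  reach <- function(p) {
    M <- diag(n)
    for (t in seq_len(p)) M <- M %*% A
    M
  }
  A1 <- A; A2 <- reach(2); A3 <- reach(3)
  dist_le <- function(i, j, p) {
    if (p >= 1 && A1[i, j] > 0) return(1)
    if (p >= 2 && A2[i, j] > 0) return(2)
    if (p >= 3 && A3[i, j] > 0) return(3)
    Inf
  }
  at <- db$atom_types
  slot <- function(tp, s) {
    r <- at[at$name == tp, ]
    c(r$sqrt_c12_1, r$sqrt_c12_2, r$sqrt_c12_3)[s]
  }
  q <- top$atoms$charge
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    g <- dist_le(i, j, 3)
    if (g <= 2) next
    r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    ti <- top$atoms$type[i]; tj <- top$atoms$type[j]
    ri <- at[at$name == ti, ]; rj <- at[at$name == tj, ]
    if (g == 3) {
      ## which dihedral spans the central bond of the 3-bond path?
      rbspan <- FALSE
      for (d in top$dihedrals) {
        if (d$type != "rb") next
        jk <- sort(c(d$j, d$k))
        ## i-j path's central bond: find mid atoms a,b with i~a~b~j
        for (a in seq_len(n)) for (b2 in seq_len(n)) {
          if (A1[i, a] && A1[a, b2] && A1[b2, j] &&
              identical(sort(c(a, b2)), jk)) rbspan <- TRUE
        }
      }
      if (rbspan) next
      c6 <- ri$sqrt_c6_14 * rj$sqrt_c6_14
      c12 <- ri$sqrt_c12_14 * rj$sqrt_c12_14
    } else {
      sel_i <- db$selection$i_slot; sel_j <- db$selection$j_slot
      new_types <- colnames(sel_i)
      if (tj %in% new_types) {
        c12 <- slot(ti, sel_i[ti, tj]) * slot(tj, sel_j[ti, tj])
      } else {
        c12 <- slot(tj, sel_i[tj, ti]) * slot(ti, sel_j[tj, ti])
      }
      if (ri$sqrt_c6 == 0 || rj$sqrt_c6 == 0) c12 <- c12 * 1  # LJ-null has 0 slots
      if (is.na(c12)) c12 <- 0
      c6 <- ri$sqrt_c6 * rj$sqrt_c6
    }
    if (is.na(c6)) c6 <- 0
    e <- e + c12 / r^12 - c6 / r^6 + 138.935458 * q[i] * q[j] / r
  }
  e
}

# random distorted conformation of a species: internals jittered around a
# reasonable reference, bonds at b0 (constrained bonds carry no energy either
# way)
random_conformation <- function(top) {
  int <- reference_internals(top, dihedrals = stats::runif(1, -180, 180))
  for (nm in names(int)) {
    if (startsWith(nm, "ang_")) {
      int[nm] <- min(175, max(5, int[nm] + stats::runif(1, -25, 25)))
    } else {
      int[nm] <- int[nm] + stats::runif(1, -180, 180)
    }
  }
  build_conformation(top, int)
}
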
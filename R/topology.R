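## Molecular topologies: construction from the database, exclusion and 1-4
## derivation from the bonded graph.

## BFS graph distances over the bond list (unit edge weights).
.graph_distances <- function(n, bonds) {
  adj <- vector("list", n)
  for (b in seq_len(nrow(bonds))) {
    i <- bonds$i[b]; j <- bonds$j[b]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  d <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d[s, s] <- 0
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) if (d[s, w] > d[s, v] + 1) {
        d[s, w] <- d[s, v] + 1
        queue <- c(queue, w)
      }
    }
  }
  d
}

## For a distance-3 pair, the dihedral type spanning the central bond of the
## (unique, tree) path decides: GROMOS -> 1-4 pair, RB -> full exclusion.
## A path with no dihedral term falls back to the GROMOS default (1-4 pair).
.span_dihedral_type <- function(top, i, j, dist) {
  ## central bond = the middle edge of the i..j path; recover it by walking
  path <- .tree_path(top, i, j)
  stopifnot(length(path) == 4)
  jk <- sort(path[2:3])
  for (d in top$dihedrals) {
    if (all(sort(c(d$j, d$k)) == jk)) return(d$type)
  }
  "gromos"
}

.tree_path <- function(top, from, to) {
  n <- nrow(top$atoms)
  adj <- vector("list", n)
  for (b in seq_len(nrow(top$bonds))) {
    i <- top$bonds$i[b]; j <- top$bonds$j[b]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  prev <- rep(NA_integer_, n)
  seen <- rep(FALSE, n); seen[from] <- TRUE
  queue <- from
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    if (v == to) break
    for (w in adj[[v]]) if (!seen[w]) {
      seen[w] <- TRUE; prev[w] <- v; queue <- c(queue, w)
    }
  }
  path <- to
  while (!is.na(prev[path[1]])) path <- c(prev[path[1]], path)
  path
}

#' Retrieve a fully populated molecular topology
#'
#' Builds the topology of one parametrized species: atoms with partial
#' charges, (constrained) bonds, cosine-form angles, impropers, proper
#' dihedrals, and the nonbonded bookkeeping derived from the bonded graph.
#' First and second neighbors are excluded; third neighbors become explicit
#' 1-4 pairs with modified C12 when the spanning dihedral is a GROMOS series,
#' and are fully excluded when it is a Ryckaert-Bellemans potential.
#'
#' @param species species identifier (see [list_species()]).
#' @param variant force-field variant tag, `"53A6"` or `"54A7"` (the variant
#'   affects emitted nonbonded tables; the intramolecular model is shared).
#' @param db parameter database.
#' @return An object of class `rons_topology`: list with `species`,
#'   `formal_charge`, `variant`, data frames `atoms`, `bonds`, `angles`,
#'   `impropers`, a list `dihedrals`, and derived data frames `exclusions`
#'   (i < j) and `pairs14` (i < j, with `c6` and `c12` columns).
#' @export
#' @examples
#' top <- get_topology("HOONO")
#' top$pairs14
get_topology <- function(species, variant = c("53A6", "54A7"),
                         db = ff_database()) {
  variant <- match.arg(variant)
  raw <- db$topologies[[species]]
  if (is.null(raw)) stop("unknown species: ", species, call. = FALSE)

  atoms <- do.call(rbind, lapply(raw$atoms, function(a)
    data.frame(name = a$name, role = a$role, type = a$type,
               charge = a$charge, stringsAsFactors = FALSE)))
  bonds <- do.call(rbind, lapply(raw$bonds, function(b)
    data.frame(i = b$i, j = b$j, b0 = b$b0, kb = b$kb,
               constrained = isTRUE(b$constrained))))
  angles <- if (length(raw$angles) == 0)
    data.frame(i = integer(), j = integer(), k = integer(),
               theta0 = numeric(), k_theta = numeric())
  else do.call(rbind, lapply(raw$angles, function(a)
    data.frame(i = a$i, j = a$j, k = a$k,
               theta0 = a$theta0, k_theta = a$k_theta)))
  impropers <- if (length(raw$impropers) == 0)
    data.frame(i = integer(), j = integer(), k = integer(), l = integer(),
               xi0 = numeric(), k_xi = numeric())
  else do.call(rbind, lapply(raw$impropers, function(a)
    data.frame(i = a$i, j = a$j, k = a$k, l = a$l,
               xi0 = a$xi0, k_xi = a$k_xi)))
  dihedrals <- lapply(raw$dihedrals, function(d) {
    out <- list(i = d$i, j = d$j, k = d$k, l = d$l,
                label = d$label, type = d$type)
    if (d$type == "gromos") {
      out$terms <- do.call(rbind, lapply(d$terms, function(t)
        data.frame(m = t$m, phi0 = t$phi0, k = t$k)))
      stopifnot(all(out$terms$m >= 1))
    } else if (d$type == "rb") {
      stopifnot(length(d$c) == 6)
      out$c <- as.numeric(d$c)
    } else stop("unknown dihedral type: ", d$type)
    out
  })

  top <- list(species = species,
              formal_charge = raw$formal_charge,
              variant = variant,
              atoms = atoms, bonds = bonds, angles = angles,
              impropers = impropers, dihedrals = dihedrals)
  class(top) <- "rons_topology"

  ## derive exclusions and 1-4 pairs from graph distances
  n <- nrow(atoms)
  dmat <- .graph_distances(n, bonds)
  excl <- list(); p14 <- list()
  if (n >= 2) for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (dmat[i, j] <= 2) {
      excl[[length(excl) + 1]] <- c(i, j)
    } else if (dmat[i, j] == 3) {
      if (.span_dihedral_type(top, i, j, dmat) == "rb")
        excl[[length(excl) + 1]] <- c(i, j)
      else
        p14[[length(p14) + 1]] <- c(i, j)
    }
  }
  top$exclusions <- if (length(excl) == 0)
    data.frame(i = integer(), j = integer())
  else as.data.frame(do.call(rbind, excl)) |> stats::setNames(c("i", "j"))
  top$pairs14 <- if (length(p14) == 0)
    data.frame(i = integer(), j = integer(), c6 = numeric(), c12 = numeric())
  else {
    d <- as.data.frame(do.call(rbind, p14)) |> stats::setNames(c("i", "j"))
    d$c6  <- mapply(function(a, b) combine_c6_14(atoms$type[a], atoms$type[b], db = db),
                    d$i, d$j)
    d$c12 <- mapply(function(a, b)
      combine_c12(atoms$type[a], atoms$type[b], "one_four", db = db),
      d$i, d$j)
    d
  }
  top
}

#' @export
print.rons_topology <- function(x, ...) {
  cat(sprintf("%s (%s): %d atoms, net charge %+d e\n",
              x$species, x$variant, nrow(x$atoms), x$formal_charge))
  cat(sprintf("  %d bonds (constrained), %d angles, %d impropers, %d dihedrals; %d excluded pairs, %d 1-4 pairs\n",
              nrow(x$bonds), nrow(x$angles), nrow(x$impropers),
              length(x$dihedrals), nrow(x$exclusions), nrow(x$pairs14)))
  invisible(x)
}
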
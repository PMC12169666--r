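## Parameter database: atom types, C12 selection matrix, molecular topologies.

.db_cache <- new.env(parent = emptyenv())

.read_atomtype_table <- function(path) {
  at <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  num <- c("mass", "sqrt_c6", "sqrt_c12_1", "sqrt_c12_2", "sqrt_c12_3",
           "sqrt_c6_14", "sqrt_c12_14")
  for (cl in num) at[[cl]] <- as.numeric(at[[cl]])
  at
}

#' Load the GROMOS-RONS parameter database
#'
#' Reads the bundled parameter tables (atom types, the two-sided C12
#' repulsive-slot selection matrix, the fifteen molecular topologies, the
#' 54A7 variant overrides and the quantum-mechanical reference charges) and
#' returns them as a single database object.  The database is cached for the
#' session; `reload = TRUE` forces a re-read.
#'
#' @param reload logical; re-read the data files even if a cached copy exists.
#' @return An object of class `rons_db`: a list with elements `atom_types`
#'   (data frame, one row per atom type, RONS-specific types first),
#'   `selection` (list of two integer matrices `i_slot` and `j_slot`, rows
#'   named by partner type, columns `OP`, `OO`, `OQ`, `NQ`),
#'   `topologies` (named list of raw topology records), `variant_54a7`
#'   (renames and ion overrides for 54A7 emission), `qm_charges`
#'   (provenance-only reference charges) and `version`.
#' @export
#' @examples
#' db <- ff_database()
#' list_species(db)
ff_database <- function(reload = FALSE) {
  if (!reload && !is.null(.db_cache$db)) return(.db_cache$db)
  root <- system.file("extdata", "gromos_rons", package = "ronsff",
                      mustWork = TRUE)
  rons    <- .read_atomtype_table(file.path(root, "atomtypes_rons.tsv"))
  partner <- .read_atomtype_table(file.path(root, "atomtypes_partner_53a6.tsv"))
  rons$origin    <- "rons"
  partner$origin <- "53a6"
  atom_types <- rbind(rons, partner)

  sel <- utils::read.delim(file.path(root, "c12_selection.tsv"),
                           comment.char = "#", stringsAsFactors = FALSE)
  new_types <- c("OP", "OO", "OQ", "NQ")
  i_slot <- as.matrix(sel[, paste0("i_", new_types)])
  j_slot <- as.matrix(sel[, paste0("j_", new_types)])
  dimnames(i_slot) <- dimnames(j_slot) <- list(sel$row, new_types)

  topo <- yaml::read_yaml(file.path(root, "topologies.yaml"))

  var47 <- utils::read.delim(file.path(root, "variant_54a7.tsv"),
                             comment.char = "#", stringsAsFactors = FALSE)
  qm <- utils::read.delim(file.path(root, "qm_charges.tsv"),
                          comment.char = "#", stringsAsFactors = FALSE)

  db <- structure(list(
    atom_types   = atom_types,
    selection    = list(i_slot = i_slot, j_slot = j_slot),
    topologies   = topo$species,
    variant_54a7 = var47,
    qm_charges   = qm,
    version      = topo$version
  ), class = "rons_db")
  .db_cache$db <- db
  db
}

#' @export
print.rons_db <- function(x, ...) {
  cat(sprintf("GROMOS-RONS parameter database v%s\n", x$version))
  cat(sprintf("  %d atom types (%d RONS-specific), %d species, %d selection rows\n",
              nrow(x$atom_types), sum(x$atom_types$origin == "rons"),
              length(x$topologies), nrow(x$selection$i_slot)))
  invisible(x)
}

#' List the parametrized species
#'
#' @param db a `rons_db` object (default: the bundled database).
#' @return Character vector of species identifiers, in stable database order.
#' @export
list_species <- function(db = ff_database()) {
  names(db$topologies)
}

.atom_type_row <- function(db, type) {
  i <- match(type, db$atom_types$name)
  if (is.na(i)) stop("unknown atom type: ", type, call. = FALSE)
  db$atom_types[i, ]
}

.sqrt_c12_slots <- function(row) {
  v <- c(row$sqrt_c12_1, row$sqrt_c12_2, row$sqrt_c12_3)
  v[!is.na(v)]
}

.is_lj_null <- function(row) {
  row$sqrt_c6 == 0 && (is.na(row$sqrt_c12_1) || row$sqrt_c12_1 == 0)
}

#' Combine attractive C6 dispersion parameters
#'
#' Geometric combination rule for the attractive Lennard-Jones coefficient:
#' `C6(i,j) = sqrt(C6(i,i)) * sqrt(C6(j,j))`.
#'
#' @param type_i,type_j atom type names.
#' @param db parameter database.
#' @return C6(i,j) in kJ mol^-1 nm^6.
#' @export
#' @examples
#' combine_c6("OP", "OP")
combine_c6 <- function(type_i, type_j, db = ff_database()) {
  .atom_type_row(db, type_i)$sqrt_c6 * .atom_type_row(db, type_j)$sqrt_c6
}

## Resolve the (slot_i, slot_j) pair for a normal-range interaction.
## The selection matrix covers every (partner or RONS type) x (RONS type)
## combination; pairs of two non-RONS types are not parametrized here.
.c12_slot_pair <- function(db, type_i, type_j) {
  new_types <- colnames(db$selection$i_slot)
  sel_i <- db$selection$i_slot
  sel_j <- db$selection$j_slot
  if (type_j %in% new_types && type_i %in% rownames(sel_i)) {
    c(i = sel_i[type_i, type_j], j = sel_j[type_i, type_j])
  } else if (type_i %in% new_types && type_j %in% rownames(sel_i)) {
    p <- c(i = sel_j[type_j, type_i], j = sel_i[type_j, type_i])
    p
  } else {
    stop(sprintf("unparametrized pair: no C12 selection entry for %s-%s",
                 type_i, type_j), call. = FALSE)
  }
}

#' Combine repulsive C12 parameters
#'
#' GROMOS atom types carry up to three repulsive `sqrt(C12)` slots; the cross
#' interaction C12(i,j) is the product of one slot of each type, chosen from
#' the bundled two-sided selection matrix.  For third-neighbor (1-4)
#' interactions the dedicated modified 1-4 constants are used instead.
#'
#' @param type_i,type_j atom type names.
#' @param context `"normal"` for full-range nonbonded pairs, `"one_four"` for
#'   third-neighbor pairs.
#' @param db parameter database.
#' @return C12(i,j) in kJ mol^-1 nm^12.  A missing selection entry (or, for
#'   `one_four`, a type lacking 1-4 constants that is not LJ-null) is an
#'   error, never a silent default.
#' @export
#' @examples
#' combine_c12("OP", "OQ")              # slots (2, 3) of the two types
#' combine_c12("OP", "OQ", "one_four")  # modified 1-4 repulsion
combine_c12 <- function(type_i, type_j, context = c("normal", "one_four"),
                        db = ff_database()) {
  context <- match.arg(context)
  ri <- .atom_type_row(db, type_i)
  rj <- .atom_type_row(db, type_j)
  if (context == "one_four") {
    for (r in list(ri, rj)) {
      if (is.na(r$sqrt_c12_14) && !.is_lj_null(r))
        stop("no 1-4 parameters for atom type ", r$name, call. = FALSE)
    }
    v14 <- function(r) if (.is_lj_null(r)) 0 else r$sqrt_c12_14
    return(v14(ri) * v14(rj))
  }
  slot <- .c12_slot_pair(db, type_i, type_j)
  si <- .sqrt_c12_slots(ri)
  sj <- .sqrt_c12_slots(rj)
  if (.is_lj_null(ri) || .is_lj_null(rj)) return(0)
  if (slot["i"] > length(si) || slot["j"] > length(sj))
    stop(sprintf("C12 selection for %s-%s points at a missing slot",
                 type_i, type_j), call. = FALSE)
  si[slot["i"]] * sj[slot["j"]]
}

#' Combine C6 for third-neighbor (1-4) interactions
#'
#' @inheritParams combine_c12
#' @return C6_14(i,j) in kJ mol^-1 nm^6 from the modified 1-4 constants.
#' @export
combine_c6_14 <- function(type_i, type_j, db = ff_database()) {
  ri <- .atom_type_row(db, type_i)
  rj <- .atom_type_row(db, type_j)
  v <- function(r) {
    if (.is_lj_null(r)) return(0)
    if (is.na(r$sqrt_c6_14))
      stop("no 1-4 parameters for atom type ", r$name, call. = FALSE)
    r$sqrt_c6_14
  }
  v(ri) * v(rj)
}

#' Validate the parameter database
#'
#' Runs every structural invariant of the parameter set: positive masses and
#' the fixed oxygen/nitrogen mass assignments, non-negative dispersion and
#' positive repulsion (except LJ-null types), full two-sided coverage of the
#' C12 selection matrix with indices pointing at existing slots, symmetry of
#' the combination rules under argument swap, net-charge sums of all species
#' to 1e-6 e, symmetric and disjoint exclusion/1-4 lists, and the rule that no
#' central bond carries both a GROMOS and an RB proper dihedral.
#'
#' @param db parameter database.
#' @return A data frame of class `rons_validation` with columns `check`,
#'   `status` (`"ok"`/`"violation"`) and `detail`; one row per finding.
#' @export
#' @examples
#' rep <- validate_database()
#' subset(rep, status == "violation")
validate_database <- function(db = ff_database()) {
  rows <- list()
  note <- function(check, ok, detail) {
    rows[[length(rows) + 1]] <<- data.frame(
      check = check, status = if (ok) "ok" else "violation",
      detail = detail, stringsAsFactors = FALSE)
  }

  at <- db$atom_types
  note("atom_type_masses", all(at$mass > 0), "all masses positive")
  for (tp in c("OP", "OO", "OQ")) {
    r <- .atom_type_row(db, tp)
    note(paste0("mass_", tp), isTRUE(all.equal(r$mass, 15.999)),
         sprintf("%s mass = %g (expect 15.999)", tp, r$mass))
  }
  rq <- .atom_type_row(db, "NQ")
  note("mass_NQ", isTRUE(all.equal(rq$mass, 14.007)),
       sprintf("NQ mass = %g (expect 14.007)", rq$mass))
  note("sqrt_c6_nonnegative", all(at$sqrt_c6 >= 0), "sqrt(C6) >= 0")
  for (i in seq_len(nrow(at))) {
    r <- at[i, ]
    if (.is_lj_null(r)) next
    slots <- .sqrt_c12_slots(r)
    note(paste0("c12_positive_", r$name),
         length(slots) >= 1 && all(slots > 0),
         sprintf("%s has %d positive C12 slot(s)", r$name, length(slots)))
  }

  ## selection-matrix coverage and slot existence
  sel_i <- db$selection$i_slot
  new_types <- colnames(sel_i)
  missing_rows <- setdiff(at$name[at$origin == "53a6"], rownames(sel_i))
  note("selection_coverage_partners", length(missing_rows) == 0,
       if (length(missing_rows) == 0) "all partner types covered"
       else paste("missing:", paste(missing_rows, collapse = ", ")))
  note("selection_coverage_new_types",
       all(new_types %in% rownames(sel_i)),
       "RONS types present as rows")
  ok_idx <- TRUE; bad <- character()
  for (rn in rownames(sel_i)) for (cn in new_types) {
    vi <- db$selection$i_slot[rn, cn]; vj <- db$selection$j_slot[rn, cn]
    ri <- if (rn %in% at$name) .atom_type_row(db, rn) else NULL
    rj <- .atom_type_row(db, cn)
    ok <- vi %in% 1:3 && vj %in% 1:3 &&
      (is.null(ri) || .is_lj_null(ri) || vi <= length(.sqrt_c12_slots(ri))) &&
      (.is_lj_null(rj) || vj <= length(.sqrt_c12_slots(rj)))
    if (!ok) { ok_idx <- FALSE; bad <- c(bad, paste0(rn, "-", cn)) }
  }
  note("selection_indices_resolve", ok_idx,
       if (ok_idx) "all indices point at existing C12 slots"
       else paste("bad entries:", paste(bad, collapse = ", ")))
  op_oq <- .c12_slot_pair(db, "OP", "OQ")
  note("selection_OP_OQ", all(op_oq == c(2, 3)),
       sprintf("OP-OQ resolves to (%d, %d) (expect (2, 3))",
               op_oq["i"], op_oq["j"]))

  ## combination-rule symmetry over every pair in the matrix
  sym_ok <- TRUE; sym_bad <- character()
  for (rn in rownames(sel_i)) for (cn in new_types) {
    if (!(rn %in% at$name)) next
    a <- combine_c12(rn, cn, db = db)
    b <- combine_c12(cn, rn, db = db)
    if (!isTRUE(all.equal(a, b))) { sym_ok <- FALSE; sym_bad <- c(sym_bad, paste0(rn, "-", cn)) }
    if (!isTRUE(all.equal(combine_c6(rn, cn, db = db),
                          combine_c6(cn, rn, db = db)))) sym_ok <- FALSE
  }
  note("combination_symmetry", sym_ok,
       if (sym_ok) "combine_c6/combine_c12 symmetric for all matrix pairs"
       else paste("asymmetric:", paste(sym_bad, collapse = ", ")))

  ## per-species checks
  for (sp in list_species(db)) {
    top <- get_topology(sp, db = db)
    qsum <- sum(top$atoms$charge)
    note(paste0("net_charge_", sp), abs(qsum - top$formal_charge) < 1e-6,
         sprintf("%s net charge %.6f (formal %d)", sp, qsum, top$formal_charge))
    bad_type <- setdiff(top$atoms$type, at$name)
    note(paste0("atom_types_resolve_", sp), length(bad_type) == 0,
         if (length(bad_type) == 0) "all atom types resolve"
         else paste("unknown:", paste(bad_type, collapse = ", ")))
    excl <- top$exclusions; p14 <- top$pairs14
    key <- function(d) if (nrow(d) == 0) character() else
      paste(pmin(d$i, d$j), pmax(d$i, d$j))
    note(paste0("excl14_disjoint_", sp),
         length(intersect(key(excl), key(p14))) == 0,
         "exclusion and 1-4 lists disjoint")
    note(paste0("b0_positive_", sp), all(top$bonds$b0 > 0), "b0 > 0")
    if (nrow(top$angles) > 0)
      note(paste0("theta0_range_", sp),
           all(top$angles$theta0 > 0 & top$angles$theta0 <= 180),
           "0 < theta0 <= 180")
    ## no central bond with both a GROMOS and an RB dihedral
    if (length(top$dihedrals) > 1) {
      cb <- vapply(top$dihedrals, function(d)
        paste(sort(c(d$j, d$k)), collapse = "-"), "")
      ty <- vapply(top$dihedrals, function(d) d$type, "")
      dup <- any(vapply(unique(cb), function(b)
        length(unique(ty[cb == b])) > 1, TRUE))
      note(paste0("dihedral_forms_", sp), !dup,
           "no bond carries both GROMOS and RB potentials")
    }
  }

  rep <- do.call(rbind, rows)
  class(rep) <- c("rons_validation", class(rep))
  rep
}

#' @export
print.rons_validation <- function(x, ...) {
  nv <- sum(x$status == "violation")
  cat(sprintf("Database validation: %d checks, %d violation(s)\n",
              nrow(x), nv))
  if (nv > 0) {
    bad <- x[x$status == "violation", ]
    for (i in seq_len(nrow(bad)))
      cat(sprintf("  VIOLATION %s: %s\n", bad$check[i], bad$detail[i]))
  }
  invisible(x)
}
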
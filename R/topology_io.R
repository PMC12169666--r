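## GROMACS-dialect topology emission and round-trip parsing.
##
## Numbers are emitted with %.10g so that re-parsing reproduces the database
## values exactly and emission is byte-stable under write -> read -> write.

.fmt <- function(x) sprintf("%.10g", x)

.variant_atomtypes <- function(db, variant) {
  at <- db$atom_types
  if (variant == "54A7") {
    ov <- db$variant_54a7
    for (r in seq_len(nrow(ov))) {
      row <- ov[r, ]
      i <- match(row$name, at$name)
      if (is.na(i)) next
      if (row$kind == "rename") {
        at$name[i] <- row$new_name
      } else if (row$kind == "atomtype") {
        for (cl in c("sqrt_c6", "sqrt_c12_1", "sqrt_c12_2", "sqrt_c12_3",
                     "sqrt_c6_14", "sqrt_c12_14"))
          at[[cl]][i] <- as.numeric(row[[cl]])
      }
    }
  }
  at
}

#' Emit one species topology as GROMACS-dialect text
#'
#' Writes a `.itp`-style molecule block: atoms with charges and masses,
#' bonds as constraints (or GROMOS quartic bonds when unconstrained),
#' cosine-form angles (funct 2), harmonic impropers (funct 2), proper
#' dihedrals as GROMOS series (funct 1, one line per term) or
#' Ryckaert-Bellemans coefficients (funct 3), explicit 1-4 `[ pairs ]` lines
#' carrying their modified C6/C12, and explicit `[ exclusions ]`.
#'
#' @param topology a `rons_topology` (see [get_topology()]).
#' @param variant `"53A6"` or `"54A7"` (recorded in the header).
#' @param path optional output file; when `NULL` the text is returned.
#' @return Character vector of lines (invisibly when `path` is given).
#' @export
#' @examples
#' txt <- write_species_topology(get_topology("H2O2"))
#' cat(head(txt, 12), sep = "\n")
write_species_topology <- function(topology, variant = topology$variant,
                                   path = NULL) {
  if (!variant %in% c("53A6", "54A7"))
    stop("unknown variant: ", variant)
  top <- topology
  L <- c(
    sprintf("; ronsff molecular topology: %s", top$species),
    sprintf("; variant %s; database v%s; charges sum to %+d e",
            variant, ff_database()$version, top$formal_charge),
    "",
    "[ moleculetype ]",
    "; name  nrexcl",
    sprintf("%s  0", top$species),
    "",
    "[ atoms ]",
    "; nr  type  resnr  residue  atom  cgnr  charge  mass")
  db <- ff_database()
  for (i in seq_len(nrow(top$atoms))) {
    a <- top$atoms[i, ]
    L <- c(L, sprintf("%4d  %-5s  1  %-6s  %-4s  1  %s  %s",
                      i, a$type, top$species, a$name,
                      .fmt(a$charge), .fmt(.atom_type_row(db, a$type)$mass)))
  }
  bd <- top$bonds
  if (any(bd$constrained)) {
    L <- c(L, "", "[ constraints ]", "; i  j  funct  b0")
    for (b in which(bd$constrained))
      L <- c(L, sprintf("%4d %4d  1  %s", bd$i[b], bd$j[b], .fmt(bd$b0[b])))
  }
  if (any(!bd$constrained)) {
    L <- c(L, "", "[ bonds ]", "; i  j  funct  b0  kb")
    for (b in which(!bd$constrained))
      L <- c(L, sprintf("%4d %4d  2  %s  %s",
                        bd$i[b], bd$j[b], .fmt(bd$b0[b]), .fmt(bd$kb[b])))
  }
  an <- top$angles
  if (nrow(an) > 0) {
    L <- c(L, "", "[ angles ]", "; i  j  k  funct  theta0  k_theta")
    for (a in seq_len(nrow(an)))
      L <- c(L, sprintf("%4d %4d %4d  2  %s  %s", an$i[a], an$j[a], an$k[a],
                        .fmt(an$theta0[a]), .fmt(an$k_theta[a])))
  }
  gd <- Filter(function(d) d$type == "gromos", top$dihedrals)
  rb <- Filter(function(d) d$type == "rb", top$dihedrals)
  if (length(gd) > 0) {
    L <- c(L, "", "[ dihedrals ]", "; i  j  k  l  funct  phi0  k  m")
    for (d in gd) for (t in seq_len(nrow(d$terms)))
      L <- c(L, sprintf("%4d %4d %4d %4d  1  %s  %s  %d",
                        d$i, d$j, d$k, d$l, .fmt(d$terms$phi0[t]),
                        .fmt(d$terms$k[t]), d$terms$m[t]))
  }
  if (length(rb) > 0) {
    L <- c(L, "", "[ dihedrals ]", "; i  j  k  l  funct  c0..c5 (RB)")
    for (d in rb)
      L <- c(L, sprintf("%4d %4d %4d %4d  3  %s",
                        d$i, d$j, d$k, d$l,
                        paste(.fmt(d$c), collapse = "  ")))
  }
  im <- top$impropers
  if (nrow(im) > 0) {
    L <- c(L, "", "[ dihedrals ]", "; i  j  k  l  funct  xi0  k_xi (improper)")
    for (a in seq_len(nrow(im)))
      L <- c(L, sprintf("%4d %4d %4d %4d  2  %s  %s",
                        im$i[a], im$j[a], im$k[a], im$l[a],
                        .fmt(im$xi0[a]), .fmt(im$k_xi[a])))
  }
  p14 <- top$pairs14
  if (nrow(p14) > 0) {
    L <- c(L, "", "[ pairs ]", "; i  j  funct  c6_14  c12_14")
    for (p in seq_len(nrow(p14)))
      L <- c(L, sprintf("%4d %4d  1  %s  %s", p14$i[p], p14$j[p],
                        .fmt(p14$c6[p]), .fmt(p14$c12[p])))
  }
  ex <- top$exclusions
  if (nrow(ex) > 0 || nrow(p14) > 0) {
    L <- c(L, "", "[ exclusions ]")
    ## GROMOS convention: 1-4 pairs are excluded from the normal nonbonded
    ## list as well (their interaction comes from [ pairs ])
    all_ex <- rbind(ex, p14[, c("i", "j")])
    for (i in sort(unique(all_ex$i))) {
      js <- sort(unique(all_ex$j[all_ex$i == i]))
      L <- c(L, paste(c(sprintf("%4d", i), sprintf("%4d", js)), collapse = " "))
    }
  }
  if (is.null(path)) return(L)
  writeLines(L, path)
  invisible(L)
}

#' Emit the nonbonded parameter tables
#'
#' Writes the `[ atomtypes ]` block (self C6/C12 of every type) and the
#' explicit per-pair `[ nonbond_params ]` block for every (RONS type x
#' partner type) and (RONS x RONS) combination in the selection matrix --
#' explicit because the multi-slot C12 selection cannot be expressed by a
#' single combination rule -- plus `[ pairtypes ]` rows with the modified
#' 1-4 parameters.  The 54A7 variant applies the bundled ion-row overrides
#' and lipid-type renames.
#'
#' @param variant `"53A6"` or `"54A7"`.
#' @param path optional output file.
#' @param db parameter database.
#' @return Character vector of lines (invisibly when `path` is given).
#' @export
write_nonbonded_tables <- function(variant = c("53A6", "54A7"), path = NULL,
                                   db = ff_database()) {
  variant <- match.arg(variant)
  at <- .variant_atomtypes(db, variant)
  rename <- db$variant_54a7[db$variant_54a7$kind == "rename", ]
  disp <- function(nm) {   # selection-matrix name -> variant display name
    if (variant == "54A7" && nm %in% rename$name)
      rename$new_name[match(nm, rename$name)] else nm
  }
  row_of <- function(nm) at[match(disp(nm), at$name), ]

  L <- c(sprintf("; ronsff nonbonded tables, variant %s, database v%s",
                 variant, db$version),
         "", "[ atomtypes ]", "; name  mass  charge  ptype  c6  c12")
  for (i in seq_len(nrow(at))) {
    r <- at[i, ]
    c12 <- if (is.na(r$sqrt_c12_1)) 0 else r$sqrt_c12_1^2
    L <- c(L, sprintf("%-6s %s  0  A  %s  %s", r$name, .fmt(r$mass),
                      .fmt(r$sqrt_c6^2), .fmt(c12)))
  }

  sel_i <- db$selection$i_slot
  new_types <- colnames(sel_i)
  L <- c(L, "", "[ nonbond_params ]", "; i  j  funct  c6  c12")
  seen <- character()
  for (rn in rownames(sel_i)) for (cn in new_types) {
    key <- paste(sort(c(rn, cn)), collapse = "-")
    if (key %in% seen) next
    seen <- c(seen, key)
    ri <- row_of(rn); rj <- row_of(cn)
    if (is.na(ri$name)) stop("no constants for selection row ", rn)
    c6 <- ri$sqrt_c6 * rj$sqrt_c6
    si <- .sqrt_c12_slots(ri); sj <- .sqrt_c12_slots(rj)
    c12 <- if (.is_lj_null(ri) || .is_lj_null(rj)) 0 else
      si[sel_i[rn, cn]] * sj[db$selection$j_slot[rn, cn]]
    L <- c(L, sprintf("%-6s %-6s  1  %s  %s", disp(rn), disp(cn),
                      .fmt(c6), .fmt(c12)))
  }

  L <- c(L, "", "[ pairtypes ]", "; i  j  funct  c6_14  c12_14")
  seen <- character()
  for (rn in rownames(sel_i)) for (cn in new_types) {
    key <- paste(sort(c(rn, cn)), collapse = "-")
    if (key %in% seen) next
    seen <- c(seen, key)
    ri <- row_of(rn); rj <- row_of(cn)
    v14 <- function(r, what) if (.is_lj_null(r)) 0 else r[[what]]
    L <- c(L, sprintf("%-6s %-6s  1  %s  %s", disp(rn), disp(cn),
                      .fmt(v14(ri, "sqrt_c6_14") * v14(rj, "sqrt_c6_14")),
                      .fmt(v14(ri, "sqrt_c12_14") * v14(rj, "sqrt_c12_14"))))
  }
  if (is.null(path)) return(L)
  writeLines(L, path)
  invisible(L)
}

.parse_sections <- function(lines) {
  lines <- sub(";.*$", "", lines)
  lines <- trimws(lines)
  sections <- list()
  current <- NULL
  for (ln in lines) {
    if (ln == "") next
    m <- regmatches(ln, regexec("^\\[\\s*(\\S+)\\s*\\]$", ln))[[1]]
    if (length(m) == 2) {
      current <- m[2]
      if (is.null(sections[[current]])) sections[[current]] <- list()
      sections[[current]] <- c(sections[[current]], list(character()))
    } else {
      if (is.null(current)) stop("malformed topology: data before any section")
      k <- length(sections[[current]])
      sections[[current]][[k]] <- c(sections[[current]][[k]], ln)
    }
  }
  sections
}

#' Parse an emitted species topology back into a topology object
#'
#' Reads the dialect produced by [write_species_topology()] and reconstructs
#' the `rons_topology`, re-deriving exclusions and 1-4 pairs from the bonded
#' graph and validating the parsed 1-4 parameters and the net charge against
#' the species' formal charge.  Unknown directives and malformed sections are
#' rejected loudly.
#'
#' @param text character vector of lines, or a file path of length 1 that
#'   exists on disk.
#' @return A `rons_topology`.
#' @export
read_species_topology <- function(text) {
  if (length(text) == 1 && file.exists(text)) text <- readLines(text)
  if (length(text) == 0 || !any(grepl("\\S", text)))
    stop("empty topology input")
  secs <- .parse_sections(text)
  known <- c("moleculetype", "atoms", "constraints", "bonds", "angles",
             "dihedrals", "pairs", "exclusions")
  unknown <- setdiff(names(secs), known)
  if (length(unknown) > 0)
    stop("unknown directive(s): ", paste(unknown, collapse = ", "))
  need <- function(nm) {
    if (is.null(secs[[nm]])) stop("missing [ ", nm, " ] section")
    unlist(secs[[nm]])
  }
  sp <- strsplit(need("moleculetype")[1], "\\s+")[[1]]
  species <- sp[1]

  arows <- strsplit(need("atoms"), "\\s+")
  atoms <- do.call(rbind, lapply(arows, function(p) {
    if (length(p) != 8) stop("malformed [ atoms ] record")
    data.frame(nr = as.integer(p[1]), name = p[5], role = p[5], type = p[2],
               charge = as.numeric(p[7]), stringsAsFactors = FALSE)
  }))
  if (any(atoms$nr != seq_len(nrow(atoms))))
    stop("inconsistent atom numbering")

  bonds <- data.frame(i = integer(), j = integer(), b0 = numeric(),
                      kb = numeric(), constrained = logical())
  for (blk in c(secs$constraints, secs$bonds)) {
    for (ln in blk) {
      p <- strsplit(ln, "\\s+")[[1]]
      if (p[3] == "1" && length(p) == 4) {
        bonds <- rbind(bonds, data.frame(i = as.integer(p[1]),
                                         j = as.integer(p[2]),
                                         b0 = as.numeric(p[4]), kb = 0,
                                         constrained = TRUE))
      } else if (p[3] == "2" && length(p) == 5) {
        bonds <- rbind(bonds, data.frame(i = as.integer(p[1]),
                                         j = as.integer(p[2]),
                                         b0 = as.numeric(p[4]),
                                         kb = as.numeric(p[5]),
                                         constrained = FALSE))
      } else stop("malformed bond/constraint record: ", ln)
    }
  }
  if (max(c(bonds$i, bonds$j, 0)) > nrow(atoms))
    stop("bond index exceeds atom count")

  angles <- data.frame(i = integer(), j = integer(), k = integer(),
                       theta0 = numeric(), k_theta = numeric())
  for (blk in secs$angles) for (ln in blk) {
    p <- strsplit(ln, "\\s+")[[1]]
    if (length(p) != 6 || p[4] != "2") stop("malformed angle record: ", ln)
    angles <- rbind(angles, data.frame(i = as.integer(p[1]),
                                       j = as.integer(p[2]),
                                       k = as.integer(p[3]),
                                       theta0 = as.numeric(p[5]),
                                       k_theta = as.numeric(p[6])))
  }

  impropers <- data.frame(i = integer(), j = integer(), k = integer(),
                          l = integer(), xi0 = numeric(), k_xi = numeric())
  gromos_terms <- list()
  dihedrals <- list()
  for (blk in secs$dihedrals) for (ln in blk) {
    p <- strsplit(ln, "\\s+")[[1]]
    quad <- as.integer(p[1:4]); funct <- p[5]
    if (funct == "1" && length(p) == 8) {
      key <- paste(quad, collapse = "-")
      gromos_terms[[key]] <- rbind(gromos_terms[[key]],
                                   data.frame(m = as.integer(p[8]),
                                              phi0 = as.numeric(p[6]),
                                              k = as.numeric(p[7])))
    } else if (funct == "3" && length(p) == 11) {
      dihedrals[[length(dihedrals) + 1]] <-
        list(i = quad[1], j = quad[2], k = quad[3], l = quad[4],
             label = NA_character_, type = "rb", c = as.numeric(p[6:11]))
    } else if (funct == "2" && length(p) == 7) {
      impropers <- rbind(impropers,
                         data.frame(i = quad[1], j = quad[2], k = quad[3],
                                    l = quad[4], xi0 = as.numeric(p[6]),
                                    k_xi = as.numeric(p[7])))
    } else stop("malformed dihedral record: ", ln)
  }
  for (key in names(gromos_terms)) {
    quad <- as.integer(strsplit(key, "-")[[1]])
    dihedrals[[length(dihedrals) + 1]] <-
      list(i = quad[1], j = quad[2], k = quad[3], l = quad[4],
           label = NA_character_, type = "gromos",
           terms = gromos_terms[[key]])
  }

  qsum <- sum(atoms$charge)
  formal <- round(qsum)
  if (abs(qsum - formal) > 1e-6)
    stop(sprintf("charges sum to %.6f, not an integer formal charge", qsum))

  top <- list(species = species, formal_charge = as.integer(formal),
              variant = "53A6",
              atoms = atoms[, c("name", "role", "type", "charge")],
              bonds = bonds, angles = angles, impropers = impropers,
              dihedrals = dihedrals)
  class(top) <- "rons_topology"

  ## rebuild exclusions/1-4 from the graph, then check the [ pairs ] section
  n <- nrow(atoms)
  dmat <- .graph_distances(n, bonds)
  excl <- list(); p14 <- list()
  if (n >= 2) for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (dmat[i, j] <= 2) excl[[length(excl) + 1]] <- c(i, j)
    else if (dmat[i, j] == 3) {
      if (.span_dihedral_type(top, i, j, dmat) == "rb")
        excl[[length(excl) + 1]] <- c(i, j)
      else p14[[length(p14) + 1]] <- c(i, j)
    }
  }
  top$exclusions <- if (length(excl) == 0)
    data.frame(i = integer(), j = integer())
  else stats::setNames(as.data.frame(do.call(rbind, excl)), c("i", "j"))

  pd <- data.frame(i = integer(), j = integer(), c6 = numeric(),
                   c12 = numeric())
  for (blk in secs$pairs) for (ln in blk) {
    p <- strsplit(ln, "\\s+")[[1]]
    if (length(p) != 5 || p[3] != "1") stop("malformed pair record: ", ln)
    pd <- rbind(pd, data.frame(i = as.integer(p[1]), j = as.integer(p[2]),
                               c6 = as.numeric(p[4]), c12 = as.numeric(p[5])))
  }
  expect_keys <- sort(vapply(p14, function(p) paste(p, collapse = " "), ""))
  got_keys <- sort(paste(pd$i, pd$j))
  if (!identical(expect_keys, got_keys))
    stop("[ pairs ] section inconsistent with the bonded graph's 1-4 list")
  top$pairs14 <- pd[order(pd$i, pd$j), , drop = FALSE]
  rownames(top$pairs14) <- NULL
  top
}
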
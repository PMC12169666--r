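## Coordinate file I/O: XYZ (Angstrom on disk, nm in memory) and GRO (nm),
## both single- and multi-frame.

.element_of <- function(name) sub("[0-9]+$", "", name)

#' Read an XYZ coordinate file
#'
#' Standard XYZ: atom count, comment line, then `element x y z` records in
#' Angstrom (converted to nm on read).  Multiple concatenated frames are
#' supported.
#'
#' @param path file path.
#' @return List of frames; each frame is a list with `comment`, `atoms`
#'   (element labels) and `xyz` (N x 3 matrix, nm).
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1
  while (i <= length(lines)) {
    if (!grepl("\\S", lines[i])) { i <- i + 1; next }
    n <- as.integer(trimws(lines[i]))
    if (is.na(n)) stop("malformed XYZ: expected atom count at line ", i)
    comment <- lines[i + 1]
    block <- lines[(i + 2):(i + 1 + n)]
    parts <- strsplit(trimws(block), "\\s+")
    atoms <- vapply(parts, `[`, "", 1)
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3))) / 10
    frames[[length(frames) + 1]] <-
      list(comment = comment, atoms = atoms, xyz = xyz)
    i <- i + 2 + n
  }
  frames
}

#' Write conformations to an XYZ file
#'
#' @param frames list of frames (`atoms`, `xyz` in nm, optional `comment`]),
#'   or a single frame / `rons_conformation`.
#' @param path output path.
#' @param topology optional topology supplying element labels for bare
#'   conformations.
#' @return `path`, invisibly.  Coordinates are written in Angstrom.
#' @export
write_xyz <- function(frames, path, topology = NULL) {
  if (!is.null(frames$xyz)) frames <- list(frames)
  con <- file(path, "w"); on.exit(close(con))
  for (fr in frames) {
    atoms <- fr$atoms
    if (is.null(atoms)) {
      if (is.null(topology)) stop("element labels needed: supply a topology")
      atoms <- .element_of(topology$atoms$name)
    }
    writeLines(as.character(nrow(fr$xyz)), con)
    writeLines(if (is.null(fr$comment)) "" else fr$comment, con)
    writeLines(sprintf("%-3s %14.8f %14.8f %14.8f", atoms,
                       fr$xyz[, 1] * 10, fr$xyz[, 2] * 10, fr$xyz[, 3] * 10),
               con)
  }
  invisible(path)
}

#' Read a GRO coordinate file
#'
#' GROMACS fixed-width GRO format, nm; multiple concatenated frames are
#' supported.
#'
#' @param path file path.
#' @return List of frames; each a list with `comment`, `atoms` (atom names),
#'   `resnames`, `xyz` (N x 3, nm) and `box` (length-3 edge vector, nm).
#' @export
read_gro <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1
  while (i <= length(lines)) {
    if (!grepl("\\S", lines[i])) { i <- i + 1; next }
    comment <- lines[i]
    n <- as.integer(trimws(lines[i + 1]))
    block <- lines[(i + 2):(i + 1 + n)]
    resnames <- trimws(substr(block, 6, 10))
    atoms <- trimws(substr(block, 11, 15))
    xyz <- cbind(as.numeric(substr(block, 21, 28)),
                 as.numeric(substr(block, 29, 36)),
                 as.numeric(substr(block, 37, 44)))
    box <- as.numeric(strsplit(trimws(lines[i + 2 + n]), "\\s+")[[1]])[1:3]
    frames[[length(frames) + 1]] <- list(comment = comment, atoms = atoms,
                                         resnames = resnames, xyz = xyz,
                                         box = box)
    i <- i + 3 + n
  }
  frames
}

#' Write frames to a GRO file
#'
#' @param frames list of frames (`atoms`, `xyz` in nm, optional `resnames`,
#'   `box`, `comment`), or a single frame / `rons_conformation`.
#' @param path output path.
#' @param topology optional topology supplying atom names.
#' @return `path`, invisibly.
#' @export
write_gro <- function(frames, path, topology = NULL) {
  if (!is.null(frames$xyz)) frames <- list(frames)
  con <- file(path, "w"); on.exit(close(con))
  for (fr in frames) {
    atoms <- fr$atoms
    if (is.null(atoms)) {
      if (is.null(topology)) stop("atom names needed: supply a topology")
      atoms <- topology$atoms$name
    }
    n <- nrow(fr$xyz)
    res <- if (is.null(fr$resnames)) rep("MOL", n) else fr$resnames
    box <- if (is.null(fr$box)) c(0, 0, 0) else fr$box
    writeLines(if (is.null(fr$comment)) "ronsff frame" else fr$comment, con)
    writeLines(sprintf("%5d", n), con)
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       rep(1, n), res, atoms, seq_len(n),
                       fr$xyz[, 1], fr$xyz[, 2], fr$xyz[, 3]), con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", box[1], box[2], box[3]), con)
  }
  invisible(path)
}
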
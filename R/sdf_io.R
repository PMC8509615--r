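#' Construct / validate a 3D conformer object
#'
#' A `conformer3d` holds one explicit-hydrogen embedded structure: an atom
#' table (element symbol, x/y/z in Angstrom) and a bond table (1-based atom
#' index pair, integer order).
#'
#' @param atoms data.frame with columns element, x, y, z.
#' @param bonds data.frame with columns i, j, order (may have zero rows).
#' @param id molecule name (compound id).
#' @param source_smiles,embed_seed provenance, optional.
#' @return object of class `conformer3d`.
#' @export
conformer3d <- function(atoms, bonds, id = "mol",
                        source_smiles = NA_character_, embed_seed = NA_integer_) {
  atoms <- as.data.frame(atoms); bonds <- as.data.frame(bonds)
  if (nrow(atoms) < 1L) stop_snap("snap_value", "conformer needs at least one atom")
  if (!all(c("element", "x", "y", "z") %in% names(atoms)))
    stop_snap("snap_value", "atoms must have element,x,y,z")
  if (any(!is.finite(as.matrix(atoms[c("x", "y", "z")]))))
    stop_snap("snap_value", "non-finite coordinates")
  if (nrow(bonds) > 0L) {
    if (!all(c("i", "j", "order") %in% names(bonds)))
      stop_snap("snap_value", "bonds must have i,j,order")
    if (any(bonds$i < 1 | bonds$i > nrow(atoms) |
            bonds$j < 1 | bonds$j > nrow(atoms)))
      stop_snap("snap_value", "bond index out of range")
  } else {
    bonds <- data.frame(i = integer(0), j = integer(0), order = integer(0))
  }
  structure(list(id = as.character(id), atoms = atoms, bonds = bonds,
                 source_smiles = source_smiles,
                 embed_seed = as.integer(embed_seed)),
            class = "conformer3d")
}

#' @export
print.conformer3d <- function(x, ...) {
  cat(sprintf("<conformer3d %s: %d atoms, %d bonds>\n",
              x$id, nrow(x$atoms), nrow(x$bonds)))
  invisible(x)
}

coords_matrix <- function(conf) as.matrix(conf$atoms[c("x", "y", "z")])

fmt_counts <- function(na, nb) sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb)

#' Write conformers to an SDF V2000 file
#'
#' Fixed formatting (10.4f coordinates, constant program line) so that
#' write-read-write is byte-stable; the molecule name field carries the
#' compound id.
#'
#' @param conformers one `conformer3d` or a list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(conformers, path) {
  if (inherits(conformers, "conformer3d")) conformers <- list(conformers)
  if (length(conformers) == 0L) stop_snap("snap_value", "no conformers to write")
  blocks <- vapply(conformers, function(cf) {
    a <- cf$atoms; b <- cf$bonds
    lines <- c(
      cf$id,
      "  snapqsar          3D",
      "",
      fmt_counts(nrow(a), nrow(b)),
      sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
              a$x, a$y, a$z, a$element),
      if (nrow(b) > 0L) sprintf("%3d%3d%3d  0", b$i, b$j, b$order),
      "M  END",
      "$$$$"
    )
    paste(lines, collapse = "\n")
  }, character(1))
  writeLines(blocks, path)
  invisible(path)
}

parse_int_field <- function(s, lineno, what) {
  v <- suppressWarnings(as.integer(trimws(s)))
  if (is.na(v)) stop_snap("snap_format", "line %d: malformed %s", lineno, what)
  v
}

#' Read an SDF V2000 file
#'
#' Parses one or many records; atom count, element symbols and the bond list
#' round-trip exactly, coordinates to the 4-decimal field precision.
#' Malformed counts lines or truncated atom blocks raise a format error
#' carrying the offending line number.
#'
#' @param path SDF file path.
#' @return a single `conformer3d` if the file has one record, else a list.
#' @export
read_sdf <- function(path) {
  if (!file.exists(path)) stop_snap("snap_io", "no such file: %s", path)
  lines <- readLines(path)
  out <- list(); pos <- 1L; n <- length(lines)
  while (pos <= n) {
    # skip trailing blank lines between records
    while (pos <= n && !nzchar(trimws(lines[pos])) &&
           all(!nzchar(trimws(lines[pos:min(n, pos + 3L)])))) pos <- pos + 1L
    if (pos > n) break
    if (pos + 3L > n)
      stop_snap("snap_format", "line %d: truncated SDF header", pos)
    name <- trimws(lines[pos])
    counts_line <- lines[pos + 3L]
    if (nchar(counts_line) < 6L)
      stop_snap("snap_format", "line %d: malformed counts line", pos + 3L)
    na <- parse_int_field(substr(counts_line, 1, 3), pos + 3L, "atom count")
    nb <- parse_int_field(substr(counts_line, 4, 6), pos + 3L, "bond count")
    a0 <- pos + 4L
    if (a0 + na - 1L > n)
      stop_snap("snap_format", "line %d: atom block truncated (%d atoms declared)",
                n, na)
    atom_lines <- lines[seq_len(na) + a0 - 1L]
    if (any(nchar(atom_lines) < 34L)) {
      bad <- a0 - 1L + which(nchar(atom_lines) < 34L)[1L]
      stop_snap("snap_format", "line %d: malformed atom line", bad)
    }
    xyz <- suppressWarnings(vapply(atom_lines, function(s) {
      as.numeric(c(substr(s, 1, 10), substr(s, 11, 20), substr(s, 21, 30)))
    }, numeric(3)))
    if (any(is.na(xyz))) {
      bad <- a0 - 1L + which(colSums(is.na(xyz)) > 0)[1L]
      stop_snap("snap_format", "line %d: malformed coordinates", bad)
    }
    elem <- trimws(substr(atom_lines, 32, 34))
    b0 <- a0 + na
    if (b0 + nb - 1L > n)
      stop_snap("snap_format", "line %d: bond block truncated", n)
    if (nb > 0L) {
      bond_lines <- lines[seq_len(nb) + b0 - 1L]
      bi <- vapply(seq_len(nb), function(k)
        parse_int_field(substr(bond_lines[k], 1, 3), b0 + k - 1L, "bond atom"),
        integer(1))
      bj <- vapply(seq_len(nb), function(k)
        parse_int_field(substr(bond_lines[k], 4, 6), b0 + k - 1L, "bond atom"),
        integer(1))
      bo <- vapply(seq_len(nb), function(k)
        parse_int_field(substr(bond_lines[k], 7, 9), b0 + k - 1L, "bond order"),
        integer(1))
      bonds <- data.frame(i = bi, j = bj, order = bo)
    } else bonds <- data.frame(i = integer(0), j = integer(0), order = integer(0))
    atoms <- data.frame(element = elem, x = xyz[1, ], y = xyz[2, ], z = xyz[3, ],
                        stringsAsFactors = FALSE, row.names = NULL)
    # skip to record terminator
    pos <- b0 + nb
    while (pos <= n && trimws(lines[pos]) != "$$$$") pos <- pos + 1L
    pos <- pos + 1L
    out[[length(out) + 1L]] <- conformer3d(atoms, bonds, id = name)
    # absorb blank padding before a possible next record
    while (pos <= n && !nzchar(trimws(lines[pos]))) pos <- pos + 1L
  }
  if (length(out) == 0L) stop_snap("snap_format", "no SDF records found")
  if (length(out) == 1L) out[[1L]] else out
}
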
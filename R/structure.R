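#' Molecular structure container
#'
#' A lightweight container for small molecular clusters: an atom table
#' (element, Cartesian coordinates in Angstrom, optional partial charge in
#' elementary charges, frozen flag) plus an explicit bond list. Atom indices
#' are 1-based row numbers of the atom table.
#'
#' @param atoms data.frame with columns `element`, `x`, `y`, `z` and
#'   optionally `charge` (elementary charges, `NA` if unassigned) and
#'   `frozen` (logical, default `FALSE`).
#' @param bonds two-column integer matrix of bonded atom index pairs, or
#'   `NULL` if connectivity is unknown (it can be inferred later from
#'   distance cutoffs).
#' @param title character title carried through file I/O.
#' @return An object of class `mol_structure`.
#' @seealso [read_structure()], [infer_bonds()], [detect_exchangeable()]
#' @export
mol_structure <- function(atoms, bonds = NULL, title = "") {
  stopifnot(is.data.frame(atoms))
  need <- c("element", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss) > 0L) {
    stop("atom table lacks column(s): ", paste(miss, collapse = ", "))
  }
  atoms$element <- normalize_element(atoms$element)
  if (is.null(atoms$charge)) atoms$charge <- NA_real_
  if (is.null(atoms$frozen)) atoms$frozen <- FALSE
  atoms <- atoms[, c("element", "x", "y", "z", "charge", "frozen")]
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("non-finite coordinates")
  }
  rownames(atoms) <- NULL
  n <- nrow(atoms)
  if (!is.null(bonds)) {
    bonds <- normalize_bonds(bonds, n)
  }
  structure(
    list(atoms = atoms, bonds = bonds, title = as.character(title)[1]),
    class = "mol_structure"
  )
}

# canonical bond matrix: integer, i < j, unique, sorted, validated
normalize_bonds <- function(bonds, n_atoms) {
  bonds <- matrix(as.integer(bonds), ncol = 2L)
  if (nrow(bonds) == 0L) {
    return(matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("i", "j"))))
  }
  if (any(bonds < 1L | bonds > n_atoms)) {
    stop("bond references atom outside 1..", n_atoms)
  }
  if (any(bonds[, 1L] == bonds[, 2L])) stop("self-bond in bond list")
  bonds <- t(apply(bonds, 1L, sort))
  bonds <- unique(bonds)
  bonds <- bonds[order(bonds[, 1L], bonds[, 2L]), , drop = FALSE]
  dimnames(bonds) <- list(NULL, c("i", "j"))
  bonds
}

#' Normalize element symbols
#'
#' Upper-cases the first letter and lower-cases the rest ("CL" -> "Cl",
#' "n" -> "N"); strips digits and whitespace.
#'
#' @param x character vector of raw element symbols.
#' @return character vector of normalized symbols.
#' @keywords internal
normalize_element <- function(x) {
  x <- gsub("[^A-Za-z]", "", as.character(x))
  if (any(!nzchar(x))) stop("empty element symbol")
  paste0(toupper(substr(x, 1L, 1L)), tolower(substr(x, 2L, nchar(x))))
}

#' @export
print.mol_structure <- function(x, ...) {
  nb <- if (is.null(x$bonds)) "unknown" else nrow(x$bonds)
  q <- x$atoms$charge
  net <- if (all(is.na(q))) "unassigned" else sprintf("%+.3f", sum(q, na.rm = TRUE))
  cat(sprintf("<mol_structure> %s: %d atoms, %s bonds, net charge %s\n",
              if (nzchar(x$title)) x$title else "(untitled)",
              nrow(x$atoms), nb, net))
  invisible(x)
}

#' Number of atoms
#' @param s a `mol_structure`.
#' @return integer atom count.
#' @export
n_atoms <- function(s) nrow(s$atoms)

#' Coordinate matrix
#' @param s a `mol_structure`.
#' @return numeric n x 3 matrix (Angstrom).
#' @export
coords <- function(s) {
  m <- as.matrix(s$atoms[, c("x", "y", "z")])
  dimnames(m) <- list(NULL, c("x", "y", "z"))
  m
}

#' Bond lengths of a structure
#' @param s a `mol_structure` with bonds.
#' @return numeric vector of bond lengths (Angstrom), one per bond row.
#' @export
bond_lengths <- function(s) {
  if (is.null(s$bonds) || nrow(s$bonds) == 0L) return(numeric(0))
  xyz <- coords(s)
  d <- xyz[s$bonds[, 1L], , drop = FALSE] - xyz[s$bonds[, 2L], , drop = FALSE]
  sqrt(rowSums(d * d))
}

# distance cutoff (Angstrom) used for bond perception when no explicit
# connectivity is available; H-H pairs never bond
bond_cutoff <- function(e1, e2) {
  h1 <- e1 == "H"
  h2 <- e2 == "H"
  if (h1 && h2) return(0)
  if (h1 || h2) {
    other <- if (h1) e2 else e1
    if (other %in% c("N", "O")) return(1.25)
    return(1.35) # C-H and other X-H
  }
  1.85 # heavy-heavy
}

#' Infer bonds from interatomic distances
#'
#' Distance-cutoff bond perception for structures read without explicit
#' connectivity (XYZ, PDB lacking CONECT). Cutoffs: N-H/O-H 1.25 A,
#' other X-H 1.35 A, heavy-heavy 1.85 A; H-H pairs are never bonded.
#'
#' @param s a `mol_structure`.
#' @return the structure with its `bonds` slot populated.
#' @export
infer_bonds <- function(s) {
  n <- n_atoms(s)
  xyz <- coords(s)
  el <- s$atoms$element
  pairs <- list()
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        cut <- bond_cutoff(el[i], el[j])
        if (cut <= 0) next
        d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
        if (d <= cut) pairs[[length(pairs) + 1L]] <- c(i, j)
      }
    }
  }
  s$bonds <- normalize_bonds(
    if (length(pairs)) do.call(rbind, pairs) else matrix(integer(0), ncol = 2L),
    n
  )
  s
}

#' Read a molecular structure from PDB or XYZ
#'
#' PDB files are parsed with \pkg{bio3d}; CONECT records, which bio3d
#' discards, are recovered from the raw file so explicit connectivity wins
#' over distance-based perception. XYZ files follow the standard
#' count/title/atom-lines layout. When no explicit bonds are present they
#' are inferred with [infer_bonds()].
#'
#' @param path file path.
#' @param format `"pdb"`, `"xyz"`, or `"auto"` (by file extension).
#' @return A `mol_structure` with atoms and bonds populated. Charges are
#'   `NA`; attach them with [set_charges()].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "xyz")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, pdb = "pdb", ent = "pdb", xyz = "xyz",
                     stop("cannot guess format from extension '", ext, "'"))
  }
  if (format == "pdb") read_structure_pdb(path) else read_structure_xyz(path)
}

read_structure_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  el <- at$elesy
  blank <- is.na(el) | !nzchar(trimws(el))
  if (any(blank)) el[blank] <- substr(trimws(at$elety[blank]), 1L, 1L)
  atoms <- data.frame(element = trimws(el),
                      x = at$x, y = at$y, z = at$z,
                      stringsAsFactors = FALSE)
  s <- mol_structure(atoms, bonds = NULL,
                     title = basename(path))
  serial <- as.integer(at$eleno)
  bonds <- parse_conect(readLines(path, warn = FALSE), serial)
  if (is.null(bonds)) infer_bonds(s) else { s$bonds <- normalize_bonds(bonds, n_atoms(s)); s }
}

# CONECT serial fields are fixed-width, 5 columns each starting at column 7
parse_conect <- function(lines, serial_map) {
  con <- lines[startsWith(lines, "CONECT")]
  if (length(con) == 0L) return(NULL)
  pairs <- list()
  for (ln in con) {
    fields <- substring(ln, seq(7L, 27L, by = 5L), seq(11L, 31L, by = 5L))
    ids <- suppressWarnings(as.integer(trimws(fields)))
    ids <- ids[!is.na(ids)]
    if (length(ids) < 2L) next
    for (j in ids[-1L]) pairs[[length(pairs) + 1L]] <- c(ids[1L], j)
  }
  if (length(pairs) == 0L) return(NULL)
  m <- do.call(rbind, pairs)
  # map file serial numbers to row indices
  m[] <- match(m, serial_map)
  if (any(is.na(m))) stop("CONECT references unknown atom serial")
  m
}

read_structure_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2L) stop("XYZ parse error at line 1: file too short")
  n <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (is.na(n) || n < 1L) stop("XYZ parse error at line 1: bad atom count")
  if (length(lines) < n + 2L) {
    stop("XYZ parse error: expected ", n + 2L, " lines, found ", length(lines))
  }
  title <- lines[2L]
  el <- character(n); xyz <- matrix(NA_real_, n, 3L)
  for (k in seq_len(n)) {
    toks <- strsplit(trimws(lines[k + 2L]), "[[:space:]]+")[[1L]]
    if (length(toks) < 4L) stop("XYZ parse error at line ", k + 2L, ": need 'El x y z'")
    v <- suppressWarnings(as.numeric(toks[2:4]))
    if (any(is.na(v))) stop("XYZ parse error at line ", k + 2L, ": bad coordinate")
    el[k] <- toks[1L]; xyz[k, ] <- v
  }
  s <- mol_structure(
    data.frame(element = el, x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
               stringsAsFactors = FALSE),
    bonds = NULL, title = title
  )
  infer_bonds(s)
}

#' Write a molecular structure to PDB or XYZ
#'
#' PDB output uses HETATM records (residue LIG, chain A) with CONECT rows
#' for every explicit bond; coordinates carry the format's native 3-decimal
#' precision. Partial charges do not fit either format and go in a sidecar
#' CSV via [write_charges()].
#'
#' @param s a `mol_structure`.
#' @param path output file path.
#' @param format `"pdb"`, `"xyz"`, or `"auto"` (by extension).
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path, format = c("auto", "pdb", "xyz")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, pdb = "pdb", xyz = "xyz",
                     stop("cannot guess format from extension '", ext, "'"))
  }
  lines <- if (format == "pdb") format_pdb(s) else format_xyz(s)
  writeLines(lines, path)
  invisible(path)
}

format_pdb <- function(s) {
  at <- s$atoms
  n <- nrow(at)
  name <- substr(paste0(at$element, seq_len(n)), 1L, 4L)
  rec <- sprintf(
    "HETATM%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(n), name, "LIG", "A", 1L, at$x, at$y, at$z, 1, 0,
    toupper(at$element)
  )
  con <- character(0)
  if (!is.null(s$bonds) && nrow(s$bonds) > 0L) {
    nb <- split(c(s$bonds[, 2L], s$bonds[, 1L]),
                c(s$bonds[, 1L], s$bonds[, 2L]))
    for (i in sort(as.integer(names(nb)))) {
      neigh <- sort(unique(nb[[as.character(i)]]))
      for (chunk in split(neigh, ceiling(seq_along(neigh) / 4L))) {
        con <- c(con, paste0(sprintf("CONECT%5d", i),
                             paste(sprintf("%5d", chunk), collapse = "")))
      }
    }
  }
  c(rec, con, "END")
}

format_xyz <- function(s) {
  at <- s$atoms
  c(as.character(nrow(at)),
    s$title,
    sprintf("%-2s %14.8f %14.8f %14.8f", at$element, at$x, at$y, at$z))
}

#' Write / read partial charges as a sidecar CSV
#'
#' Columns: `index` (1-based atom index), `element`, `charge` (elementary
#' charges). The companion of [write_structure()], since neither PDB nor
#' XYZ carries charges.
#'
#' @param s a `mol_structure` with charges assigned.
#' @param path CSV path.
#' @return `path` invisibly (`write_charges`); a data.frame (`read_charges`).
#' @export
write_charges <- function(s, path) {
  df <- data.frame(index = seq_len(n_atoms(s)),
                   element = s$atoms$element,
                   charge = s$atoms$charge)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_charges
#' @export
read_charges <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("index", "element", "charge")
  if (!all(need %in% names(df))) {
    stop("charge CSV needs columns: ", paste(need, collapse = ", "))
  }
  df
}

#' Attach partial charges to a structure
#'
#' @param s a `mol_structure`.
#' @param charges data.frame as returned by [read_charges()].
#' @return the structure with charges set; errors if an element symbol in
#'   the charge table disagrees with the structure.
#' @export
set_charges <- function(s, charges) {
  idx <- as.integer(charges$index)
  if (any(idx < 1L | idx > n_atoms(s))) stop("charge index out of range")
  mism <- normalize_element(charges$element) != s$atoms$element[idx]
  if (any(mism)) {
    stop("element mismatch at index ", paste(idx[mism], collapse = ", "))
  }
  s$atoms$charge[idx] <- as.numeric(charges$charge)
  s
}
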
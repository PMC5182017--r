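# Neutral-atom electron counts for elements encountered in protein models.
.electrons <- c(H = 1, C = 6, N = 7, O = 8, F = 9, NA. = 11, MG = 12, P = 15,
                S = 16, CL = 17, K = 19, CA. = 20, MN = 25, FE = 26, ZN = 30,
                SE = 34, BR = 35, I = 53)

element_electrons <- function(element) {
  key <- toupper(element)
  key[key %in% c("NA", "CA")] <- paste0(key[key %in% c("NA", "CA")], ".")
  n <- .electrons[key]
  if (any(is.na(n)))
    stop("no electron count for element(s): ",
         paste(unique(element[is.na(n)]), collapse = ", "))
  as.integer(unname(n))
}

# Infer an element symbol from a PDB atom name (ATOM records only: the
# leading character of the stripped name, except two-letter cases like SE).
element_from_name <- function(name) {
  nm <- toupper(trimws(name))
  el <- substr(nm, 1, 1)
  el[substr(nm, 1, 2) == "SE"] <- "SE"
  el
}

new_structure <- function(atoms, cell, identifier = "") {
  stopifnot(is.data.frame(atoms), inherits(cell, "xtal_cell"))
  if (nrow(atoms) == 0) stop("a structure must contain at least one atom")
  frac <- orth_to_frac(cell, as.matrix(atoms[, c("x", "y", "z")]))
  if (any(!is.finite(frac))) stop("non-finite fractional coordinates")
  key <- paste(atoms$chain, atoms$resno, atoms$name, atoms$altloc)
  if (anyDuplicated(key))
    stop("duplicate atom identifier (chain, resno, name, altloc): ",
         key[anyDuplicated(key)])
  s <- list(atoms = atoms, cell = cell, identifier = identifier)
  class(s) <- "xtal_structure"
  s
}

#' Build a structure from an atom table
#'
#' Convenience constructor for programmatic models: fills in serials,
#' altlocs, elements (inferred from atom names), unit occupancies and
#' B-factors where the table omits them.
#'
#' @param atoms Data frame with at least name, resname, chain, resno, x,
#'   y, z columns.
#' @param cell An \code{xtal_cell}.
#' @param identifier Text label.
#' @return An \code{xtal_structure}.
#' @export
xtal_structure <- function(atoms, cell, identifier = "model") {
  if (is.null(atoms$serial)) atoms$serial <- seq_len(nrow(atoms))
  if (is.null(atoms$altloc)) atoms$altloc <- ""
  if (is.null(atoms$element)) atoms$element <- element_from_name(atoms$name)
  if (is.null(atoms$occ)) atoms$occ <- 1
  if (is.null(atoms$b)) atoms$b <- 15
  if (is.null(atoms$het)) atoms$het <- FALSE
  atoms$n_electrons <- element_electrons(atoms$element)
  new_structure(atoms, cell, identifier)
}

#' @export
print.xtal_structure <- function(x, ...) {
  cat(sprintf("<xtal_structure '%s'> %d atoms, %d residues\n", x$identifier,
              nrow(x$atoms), length(unique(paste(x$atoms$chain, x$atoms$resno)))))
  print(x$cell)
  invisible(x)
}

#' Read a coordinate model from a PDB file
#'
#' Parses ATOM/HETATM records and the mandatory CRYST1 cell. Elements are
#' taken from columns 77-78 when present, otherwise inferred from the atom
#' name. Coordinates are orthogonal Angstrom.
#'
#' @param path Path to a PDB file.
#' @return An \code{xtal_structure}: a list with \code{atoms} (data.frame
#'   with columns serial, name, altloc, resname, chain, resno, element, x,
#'   y, z, occ, b, n_electrons), \code{cell} and \code{identifier}.
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  icryst <- which(rec == "CRYST1")
  if (length(icryst) == 0)
    stop("PDB file has no CRYST1 record (unit cell required): ", path)
  cl <- lines[icryst[1]]
  cp <- suppressWarnings(as.numeric(c(
    substr(cl, 7, 15), substr(cl, 16, 24), substr(cl, 25, 33),
    substr(cl, 34, 40), substr(cl, 41, 47), substr(cl, 48, 54))))
  if (any(is.na(cp)))
    stop("unparseable CRYST1 record at line ", icryst[1])
  cell <- unit_cell(cp[1], cp[2], cp[3], cp[4], cp[5], cp[6])

  iat <- which(rec %in% c("ATOM  ", "HETATM"))
  if (length(iat) == 0) stop("no ATOM/HETATM records in ", path)
  al <- lines[iat]
  num <- function(from, to, what) {
    v <- suppressWarnings(as.numeric(substr(al, from, to)))
    if (any(is.na(v)))
      stop("unparseable ", what, " in ATOM record at line ",
           iat[which(is.na(v))[1]])
    v
  }
  element <- trimws(substr(al, 77, 78))
  name <- trimws(substr(al, 13, 16))
  element[element == ""] <- element_from_name(name[element == ""])
  atoms <- data.frame(
    serial = as.integer(num(7, 11, "serial")),
    name = name,
    altloc = trimws(substr(al, 17, 17)),
    resname = trimws(substr(al, 18, 20)),
    chain = substr(al, 22, 22),
    resno = as.integer(num(23, 26, "residue number")),
    element = element,
    x = num(31, 38, "x"), y = num(39, 46, "y"), z = num(47, 54, "z"),
    occ = num(55, 60, "occupancy"),
    b = num(61, 66, "B-factor"),
    het = rec[iat] == "HETATM",
    stringsAsFactors = FALSE
  )
  if (any(atoms$occ < 0 | atoms$occ > 1))
    stop("occupancy outside [0,1] at line ",
         iat[which(atoms$occ < 0 | atoms$occ > 1)[1]])
  atoms$n_electrons <- element_electrons(atoms$element)
  new_structure(atoms, cell, identifier = sub("\\.pdb$", "", basename(path)))
}

#' Write a coordinate model to a PDB file
#'
#' Fixed-column PDB text with a CRYST1 record. Coordinates are written to
#' 3 decimal places and occupancy/B to 2: re-reading reproduces fields to
#' that format precision (occupancy 0.333 becomes 0.33).
#'
#' @param structure An \code{xtal_structure}.
#' @param path Output file path.
#' @export
write_pdb <- function(structure, path) {
  a <- structure$atoms
  cl <- structure$cell
  cryst <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                   cl$a, cl$b, cl$c, cl$alpha, cl$beta, cl$gamma)
  # PDB name field: 1-letter elements start in column 14
  nm <- ifelse(nchar(a$element) == 1 & nchar(a$name) < 4,
               sprintf(" %-3s", a$name), sprintf("%-4s", a$name))
  rec <- ifelse(a$het, "HETATM", "ATOM  ")
  lines <- sprintf("%s%5d %s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   rec, a$serial, nm, a$altloc, a$resname, a$chain, a$resno,
                   a$x, a$y, a$z, a$occ, a$b, a$element)
  writeLines(c(cryst, lines, "END"), path)
  invisible(path)
}

#' Select atoms by atom-type key
#'
#' An atom type is the pair (residue name, atom name), e.g. the set of all
#' Tyr OH hydroxyl oxygens in a structure is \code{atom_type_key("TYR",
#' "OH")}. Matching is exact: (GLU, OE1) never matches OE2.
#'
#' @param structure An \code{xtal_structure}.
#' @param key An \code{atom_type_key}.
#' @return Data frame of matching atom rows (possibly zero rows).
#' @export
select_atoms <- function(structure, key) {
  a <- structure$atoms
  a[a$resname == key$resname & a$name == key$atom, , drop = FALSE]
}

#' @rdname select_atoms
#' @param resname Three-letter residue code.
#' @param atom Atom name within the residue.
#' @export
atom_type_key <- function(resname, atom) {
  if (!nzchar(resname) || !nzchar(atom))
    stop("atom_type_key fields must be non-empty")
  structure(list(resname = resname, atom = atom), class = "atom_type_key")
}

#' @export
format.atom_type_key <- function(x, ...) paste0(x$resname, "-", x$atom)

#' @export
print.atom_type_key <- function(x, ...) {
  cat(format(x), "\n"); invisible(x)
}

# Default analysis subset: heavy atoms, single-conformer (altloc '' or 'A'),
# polymer residues only unless include_het.
analysis_atoms <- function(structure, include_het = FALSE,
                           include_altloc = FALSE) {
  a <- structure$atoms
  keep <- a$element != "H"
  if (!include_altloc) keep <- keep & a$altloc %in% c("", "A")
  if (!include_het) keep <- keep & !a$het
  a[keep, , drop = FALSE]
}
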
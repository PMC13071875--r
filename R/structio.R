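# Structure I/O: PDB reading/writing, distance-based receptor subsetting, and
# search-box definition around a reference atom.  Parsing and serialization
# are delegated to bio3d; this layer adds the atom table the docking and
# trajectory code consume (partial charges, van der Waals radii) and the
# dialect rules (first model only, altloc 'A' or blank).

# van der Waals radii (Angstrom), Bondi-style consensus values.
.vdw_radii <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
  F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90, B = 1.92,
  SI = 2.10, "NA" = 2.27, K = 2.75, MG = 1.73, CA = 2.31, ZN = 1.39,
  FE = 2.00, MN = 2.00
)
.default_vdw <- 1.70

#' Look up van der Waals radii by element symbol
#'
#' Unknown elements fall back to the carbon-like default of 1.70 Angstrom.
#'
#' @param element character vector of element symbols (case-insensitive).
#' @return numeric vector of radii in Angstrom.
#' @export
vdw_radius <- function(element) {
  r <- .vdw_radii[toupper(element)]
  r[is.na(r)] <- .default_vdw
  unname(r)
}

.guess_element <- function(name) {
  # strip digits/spaces; two-letter symbols only when they are known elements
  nm <- toupper(gsub("[^A-Za-z]", "", name))
  two <- substr(nm, 1, 2)
  one <- substr(nm, 1, 1)
  ifelse(two %in% names(.vdw_radii) & !(one %in% c("C", "N", "O", "H", "S", "P")),
         two, one)
}

.as_pdb_input <- function(pdb) {
  # Accept a file path or raw PDB text (detected by an embedded newline).
  if (length(pdb) > 1L || grepl("\n", pdb, fixed = TRUE)) {
    f <- tempfile(fileext = ".pdb")
    writeLines(if (length(pdb) > 1L) pdb else strsplit(pdb, "\n", fixed = TRUE)[[1L]], f)
    f
  } else {
    if (!file.exists(pdb)) stop("PDB input is neither text nor an existing file: ", pdb)
    pdb
  }
}

.validate_pdb_lines <- function(file) {
  lines <- readLines(file, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_atom)) stop("empty input: no ATOM/HETATM records found")
  idx <- which(is_atom)
  for (i in idx) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop(sprintf("malformed ATOM/HETATM record at line %d: fewer than 54 columns", i))
    xyz <- c(substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54))
    if (anyNA(suppressWarnings(as.numeric(xyz))))
      stop(sprintf("malformed ATOM/HETATM record at line %d: non-numeric coordinates", i))
  }
  invisible(lines)
}

.atoms_from_bio3d <- function(at, xyz1) {
  n <- nrow(at)
  crd <- matrix(xyz1, ncol = 3, byrow = TRUE)
  elem <- at$elesy
  bad <- is.na(elem) | elem == ""
  if (any(bad)) elem[bad] <- .guess_element(at$elety[bad])
  data.frame(
    serial = at$eleno,
    name = at$elety,
    altloc = ifelse(is.na(at$alt), "", at$alt),
    residue_name = at$resid,
    chain_id = ifelse(is.na(at$chain), "", at$chain),
    residue_number = at$resno,
    x = crd[, 1], y = crd[, 2], z = crd[, 3],
    element = toupper(elem),
    charge = 0,
    radius = vdw_radius(elem),
    stringsAsFactors = FALSE
  )
}

#' Read a structure from PDB text or file
#'
#' Reads ATOM/HETATM records of the *first* model only.  Alternate locations
#' other than blank or 'A' are dropped.  Partial charges default to 0 (see
#' [read_charges()] for the sidecar format) and van der Waals radii come from
#' a fixed element table.
#'
#' @param pdb a file path, a single string of PDB text, or a character vector
#'   of PDB lines.
#' @param charges optional path to a two-column whitespace-delimited sidecar
#'   file of `serial charge` rows.
#' @return an object of class `Structure`: a list with `atoms` (data frame)
#'   and `title`.
#' @export
read_structure <- function(pdb, charges = NULL) {
  file <- .as_pdb_input(pdb)
  .validate_pdb_lines(file)
  p <- suppressWarnings(bio3d::read.pdb(file, multi = FALSE, verbose = FALSE))
  keep <- is.na(p$atom$alt) | p$atom$alt %in% c("", "A")
  at <- p$atom[keep, , drop = FALSE]
  if (nrow(at) == 0L) stop("empty input: no atoms left after altloc filtering")
  xyz1 <- p$xyz[1, atom2xyz(which(keep))]
  atoms <- .atoms_from_bio3d(at, xyz1)
  s <- structure(list(atoms = atoms, title = ""), class = "Structure")
  if (!is.null(charges)) s <- apply_charges(s, read_charges(charges))
  s
}

# bio3d exports atom2xyz but keep a local alias so selection math is explicit
atom2xyz <- function(i) as.vector(rbind(3 * i - 2, 3 * i - 1, 3 * i))

#' @export
print.Structure <- function(x, ...) {
  cat(sprintf("Structure: %d atoms, %d residues, chains: %s\n",
              nrow(x$atoms),
              nrow(unique(x$atoms[, c("chain_id", "residue_number")])),
              paste(sort(unique(x$atoms$chain_id)), collapse = " ")))
  invisible(x)
}

#' Extract an n x 3 coordinate matrix from a Structure
#' @param s a `Structure`.
#' @return numeric matrix with columns x, y, z.
#' @export
coords <- function(s) {
  stopifnot(inherits(s, "Structure") || is.data.frame(s))
  a <- if (is.data.frame(s)) s else s$atoms
  as.matrix(a[, c("x", "y", "z")])
}

#' Read a sidecar partial-charge file
#'
#' Whitespace-delimited rows of `serial charge`; lines starting with `#` are
#' comments.
#'
#' @param path file path.
#' @return data frame with columns `serial`, `charge`.
#' @export
read_charges <- function(path) {
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           col.names = c("serial", "charge"))
  if (anyNA(tab$charge)) stop("non-numeric charge in sidecar file: ", path)
  tab
}

#' Apply sidecar charges to a Structure by atom serial
#' @param s a `Structure`.
#' @param charges data frame from [read_charges()].
#' @return the Structure with updated `charge` column.
#' @export
apply_charges <- function(s, charges) {
  i <- match(charges$serial, s$atoms$serial)
  if (anyNA(i)) stop("sidecar refers to unknown atom serial(s): ",
                     paste(charges$serial[is.na(i)], collapse = ", "))
  s$atoms$charge[i] <- charges$charge
  s
}

#' Write a Structure to a PDB file
#'
#' Coordinates are written with the standard fixed-column precision
#' (3 decimals), so read/write round-trips are exact at that precision.
#'
#' @param s a `Structure`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_structure <- function(s, file) {
  stopifnot(inherits(s, "Structure"))
  a <- s$atoms
  bio3d::write.pdb(
    file = file,
    xyz = as.vector(t(coords(s))),
    resno = a$residue_number, resid = a$residue_name,
    eleno = a$serial, elety = a$name, chain = a$chain_id,
    elesy = a$element
  )
  invisible(file)
}

#' Select atoms within a distance cutoff of a point
#'
#' Closed boundary: atoms exactly at the cutoff distance are included.
#' Original atom order is preserved; an empty result is valid.
#'
#' @param s a `Structure`.
#' @param center numeric length-3 center (Angstrom).
#' @param cutoff non-negative distance cutoff (Angstrom).
#' @param chains optional character vector restricting the selection to
#'   specific chain identifiers.
#' @return a `Structure` holding the selected atoms.
#' @export
select_within <- function(s, center, cutoff, chains = NULL) {
  stopifnot(inherits(s, "Structure"), length(center) == 3, cutoff >= 0)
  d2 <- colSums((t(coords(s)) - center)^2)
  keep <- d2 <= cutoff^2
  if (!is.null(chains)) keep <- keep & s$atoms$chain_id %in% chains
  structure(list(atoms = s$atoms[keep, , drop = FALSE], title = s$title),
            class = "Structure")
}

#' Construct an axis-aligned cubic search box
#' @param center numeric length-3 (Angstrom).
#' @param edge positive edge length (Angstrom); default 15.
#' @return an object of class `SearchBox` with `center` and `edge`.
#' @export
search_box <- function(center, edge = 15) {
  stopifnot(length(center) == 3, is.finite(edge), edge > 0)
  structure(list(center = as.numeric(center), edge = as.numeric(edge)),
            class = "SearchBox")
}

#' @export
print.SearchBox <- function(x, ...) {
  cat(sprintf("SearchBox: edge %.2f A centered at (%.2f, %.2f, %.2f)\n",
              x$edge, x$center[1], x$center[2], x$center[3]))
  invisible(x)
}

#' Box bounds as a 2 x 3 matrix (rows: lower, upper)
#' @param box a `SearchBox`.
#' @export
box_bounds <- function(box) {
  rbind(lower = box$center - box$edge / 2, upper = box$center + box$edge / 2)
}

#' Is a point inside a search box (closed interval per axis)?
#' @param box a `SearchBox`.
#' @param p numeric length-3 point.
#' @export
in_box <- function(box, p) {
  b <- box_bounds(box)
  all(p >= b[1, ] - 1e-9) && all(p <= b[2, ] + 1e-9)
}

#' Define the docking search box from a single named atom
#'
#' The box is centered on the unique atom matching (chain, residue number,
#' atom name); zero matches or more than one match are errors, never a
#' silent pick.
#'
#' @param s a `Structure`.
#' @param chain_id chain identifier.
#' @param residue_number residue number as deposited (no renumbering).
#' @param atom_name PDB atom name, e.g. `"CZ"`.
#' @param edge box edge length in Angstrom (default 15).
#' @return a `SearchBox`.
#' @export
box_from_atom <- function(s, chain_id, residue_number, atom_name, edge = 15) {
  a <- s$atoms
  hit <- which(a$chain_id == chain_id &
               a$residue_number == residue_number &
               trimws(a$name) == trimws(atom_name))
  if (length(hit) == 0L)
    stop(sprintf("no atom matches chain %s, residue %d, name %s",
                 chain_id, residue_number, atom_name))
  if (length(hit) > 1L)
    stop(sprintf("ambiguous atom: %d atoms match chain %s, residue %d, name %s",
                 length(hit), chain_id, residue_number, atom_name))
  search_box(unlist(a[hit, c("x", "y", "z")], use.names = FALSE), edge)
}

#' Serialize a SearchBox to JSON
#' @param box a `SearchBox`.
#' @param file optional output path; if `NULL` the JSON string is returned.
#' @export
box_to_json <- function(box, file = NULL) {
  j <- jsonlite::toJSON(list(center = box$center, edge = box$edge),
                        auto_unbox = TRUE, digits = NA)
  if (is.null(file)) return(j)
  writeLines(j, file)
  invisible(file)
}

#' Read a SearchBox from JSON
#' @param x a JSON string or file path produced by [box_to_json()].
#' @export
box_from_json <- function(x) {
  l <- jsonlite::fromJSON(x)
  search_box(l$center, l$edge)
}

#' Select atom indices by chain, residue and/or atom name
#'
#' Convenience selector used by the trajectory readouts.
#'
#' @param s a `Structure` (or the topology of a Trajectory).
#' @param chain,resno,elety optional filters; `NULL` means no constraint.
#' @param heavy if `TRUE`, drop hydrogens.
#' @return integer vector of atom indices (row positions in `s$atoms`).
#' @export
select_atoms <- function(s, chain = NULL, resno = NULL, elety = NULL,
                         heavy = FALSE) {
  a <- s$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chain)) keep <- keep & a$chain_id %in% chain
  if (!is.null(resno)) keep <- keep & a$residue_number %in% resno
  if (!is.null(elety)) keep <- keep & trimws(a$name) %in% trimws(elety)
  if (heavy) keep <- keep & a$element != "H"
  which(keep)
}

#' Build a Structure from an atom table
#'
#' Constructor used by the synthetic generators; fills defaults for columns
#' that are absent (serial, altloc, element-derived radius, zero charge).
#'
#' @param atoms data frame with at least `x`, `y`, `z` and `element`.
#' @param title optional title string.
#' @return a `Structure`.
#' @export
make_structure <- function(atoms, title = "") {
  n <- nrow(atoms)
  stopifnot(n > 0, all(c("x", "y", "z", "element") %in% names(atoms)))
  defaults <- list(serial = seq_len(n), name = atoms$element, altloc = "",
                   residue_name = "LIG", chain_id = "A",
                   residue_number = seq_len(n), charge = 0)
  for (nm in names(defaults)) if (is.null(atoms[[nm]])) atoms[[nm]] <- defaults[[nm]]
  if (is.null(atoms$radius)) atoms$radius <- vdw_radius(atoms$element)
  if (anyDuplicated(atoms$serial)) stop("atom serials must be unique")
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates")
  cols <- c("serial", "name", "altloc", "residue_name", "chain_id",
            "residue_number", "x", "y", "z", "element", "charge", "radius")
  structure(list(atoms = atoms[, cols], title = title), class = "Structure")
}
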
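# Residue-name dictionaries. Side-chain atom lists are the canonical
# heavy atoms beyond CB for each amino acid (used to detect incomplete
# side chains).
.aa3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")
.nuc_names <- c("A", "C", "G", "U", "DA", "DC", "DG", "DT", "DU")
.water_names <- c("HOH", "WAT", "H2O")
.dummy_names <- c("DUM")

.sidechain_atoms <- list(
  ALA = character(0),
  ARG = c("CG", "CD", "NE", "CZ", "NH1", "NH2"),
  ASN = c("CG", "OD1", "ND2"),
  ASP = c("CG", "OD1", "OD2"),
  CYS = c("SG"),
  GLN = c("CG", "CD", "OE1", "NE2"),
  GLU = c("CG", "CD", "OE1", "OE2"),
  GLY = character(0),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2"),
  ILE = c("CG1", "CG2", "CD1"),
  LEU = c("CG", "CD1", "CD2"),
  LYS = c("CG", "CD", "CE", "NZ"),
  MET = c("CG", "SD", "CE"),
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  PRO = c("CG", "CD"),
  SER = c("OG"),
  THR = c("OG1", "CG2"),
  TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
  VAL = c("CG1", "CG2")
)

.known_elements <- c("H", "C", "N", "O", "P", "S", "F", "CL", "BR", "I",
                     "SE", "FE", "ZN", "MG", "MN", "CA", "NA", "K", "CU",
                     "NI", "CO", "MO", "W", "X")

residue_category <- function(resname) {
  resname <- toupper(resname)
  out <- rep("other", length(resname))
  out[resname %in% .aa3] <- "protein"
  out[resname %in% .nuc_names] <- "nucleic"
  out[resname %in% .water_names] <- "water"
  out[resname %in% .dummy_names] <- "dummy"
  out
}

empty_atom_table <- function() {
  data.frame(chain = character(0), seqnum = integer(0), icode = character(0),
             resname = character(0), category = character(0),
             atom = character(0), element = character(0),
             x = numeric(0), y = numeric(0), z = numeric(0),
             occ = numeric(0), b = numeric(0),
             stringsAsFactors = FALSE)
}

#' Macromolecular structure model
#'
#' A structure model holds a [unit_cell()], a [space_group()] and a flat
#' atom table (one row per atom) with chain / residue identifiers. The
#' atom table is an ordinary data frame with columns `chain`, `seqnum`,
#' `icode`, `resname`, `category` (protein / nucleic / water / dummy /
#' other), `atom`, `element`, orthogonal coordinates `x`, `y`, `z` in
#' angstroms, `occ` (occupancy in `[0, 1]`) and `b` (isotropic B factor
#' in square angstroms; carries pLDDT for predicted models).
#'
#' @param cell A [unit_cell()].
#' @param spacegroup A [space_group()] or HM symbol string.
#' @param atoms Atom data frame as described above; `category` is filled
#'   from `resname` when absent.
#' @return Object of class `xtal_model`.
#' @export
structure_model <- function(cell, spacegroup = "P 1", atoms = empty_atom_table()) {
  if (!inherits(cell, "unit_cell")) stop("cell must be a unit_cell")
  if (!inherits(spacegroup, "space_group")) spacegroup <- space_group(spacegroup)
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  if (nrow(atoms)) {
    if (is.null(atoms$icode)) atoms$icode <- ""
    if (is.null(atoms$category)) atoms$category <- residue_category(atoms$resname)
    if (is.null(atoms$occ)) atoms$occ <- 1
    if (is.null(atoms$b)) atoms$b <- 20
    if (is.null(atoms$element)) atoms$element <- guess_element(atoms$atom)
    atoms$seqnum <- as.integer(atoms$seqnum)
    if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
      stop("atom positions must be finite")
    if (any(atoms$occ < 0 | atoms$occ > 1))
      stop("occupancies must lie in [0, 1]")
    bad <- !toupper(atoms$element) %in% .known_elements
    if (any(bad))
      stop("unrecognized element symbol(s): ",
           paste(unique(atoms$element[bad]), collapse = ", "))
  }
  atoms <- atoms[, names(empty_atom_table())]
  structure(list(cell = cell, spacegroup = spacegroup, atoms = atoms),
            class = "xtal_model")
}

guess_element <- function(atom_name) {
  nm <- toupper(trimws(atom_name))
  el <- substring(nm, 1, 1)
  two <- substring(nm, 1, 2)
  el[two %in% c("SE", "FE", "ZN", "MG", "MN", "CL", "BR", "NA", "CU", "NI", "CO")] <-
    two[two %in% c("SE", "FE", "ZN", "MG", "MN", "CL", "BR", "NA", "CU", "NI", "CO")]
  el
}

#' @export
print.xtal_model <- function(x, ...) {
  cat(sprintf("<xtal_model> %s, %d chain(s), %d residue(s), %d atom(s)\n",
              x$spacegroup$symbol, length(unique(x$atoms$chain)),
              n_residues(x), nrow(x$atoms)))
  print(x$cell)
  invisible(x)
}

#' @export
summary.xtal_model <- function(object, ...) {
  tab <- table(residue_table(object)$category)
  cat(sprintf("Structure model in %s\n", object$spacegroup$symbol))
  print(object$cell)
  for (nm in names(tab)) cat(sprintf("  %-8s %d residue(s)\n", nm, tab[[nm]]))
  invisible(object)
}

residue_key <- function(atoms) {
  paste(atoms$chain, atoms$seqnum, atoms$icode, sep = "|")
}

#' Residue-level view of a model
#'
#' @param model An `xtal_model`.
#' @return Data frame with one row per residue (`chain`, `seqnum`,
#'   `icode`, `resname`, `category`, `key`), in atom-table order.
#' @export
residue_table <- function(model) {
  a <- model$atoms
  if (!nrow(a)) return(cbind(empty_atom_table()[, 1:5], key = character(0)))
  key <- residue_key(a)
  first <- !duplicated(key)
  out <- a[first, c("chain", "seqnum", "icode", "resname", "category")]
  out$key <- key[first]
  rownames(out) <- NULL
  out
}

n_residues <- function(model) nrow(residue_table(model))

check_unique_residues <- function(model) {
  rt <- residue_table(model)
  dup <- duplicated(rt$key)
  if (any(dup))
    stop("duplicate residue identifiers: ", paste(rt$key[dup], collapse = ", "))
  invisible(TRUE)
}

#' Subset a model by residue
#'
#' @param model An `xtal_model`.
#' @param keys Residue keys (`"chain|seqnum|icode"`) to keep or drop.
#' @param drop If `TRUE` (default) the keys are removed; otherwise only
#'   the keys are retained.
#' @return The filtered model; chains left with no residues disappear.
#' @export
subset_residues <- function(model, keys, drop = TRUE) {
  sel <- residue_key(model$atoms) %in% keys
  if (drop) sel <- !sel
  structure_model(model$cell, model$spacegroup, model$atoms[sel, , drop = FALSE])
}

#' Append residues to a model
#'
#' @param model An `xtal_model`.
#' @param atoms Atom data frame rows to append (same columns as the
#'   model's atom table, `category`/`occ`/`b` filled when missing).
#' @export
append_residues <- function(model, atoms) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  if (is.null(atoms$icode)) atoms$icode <- ""
  if (is.null(atoms$category)) atoms$category <- residue_category(atoms$resname)
  if (is.null(atoms$occ)) atoms$occ <- 1
  if (is.null(atoms$b)) atoms$b <- 20
  if (is.null(atoms$element)) atoms$element <- guess_element(atoms$atom)
  structure_model(model$cell, model$spacegroup,
                  rbind(model$atoms, atoms[, names(empty_atom_table())]))
}

#' Drop residues of given categories
#'
#' Used by the pipeline to strip dummy atoms and waters after the
#' phase-improvement refinement.
#'
#' @param model An `xtal_model`.
#' @param categories Character vector of categories to remove.
#' @export
strip_categories <- function(model, categories = c("dummy", "water")) {
  keep <- !model$atoms$category %in% categories
  structure_model(model$cell, model$spacegroup, model$atoms[keep, , drop = FALSE])
}

atom_coords <- function(model, sel = TRUE) {
  as.matrix(model$atoms[sel, c("x", "y", "z"), drop = FALSE])
}

#' Extract coordinates of a named atom per protein residue
#'
#' @param model An `xtal_model`.
#' @param atom Atom name, e.g. `"CA"`.
#' @param chain Optional chain id filter.
#' @return Matrix of coordinates with residue keys as row names.
#' @export
named_atom_coords <- function(model, atom = "CA", chain = NULL) {
  a <- model$atoms
  sel <- a$category == "protein" & a$atom == atom
  if (!is.null(chain)) sel <- sel & a$chain == chain
  m <- as.matrix(a[sel, c("x", "y", "z"), drop = FALSE])
  rownames(m) <- residue_key(a)[sel]
  m
}

#' Translate a whole model
#'
#' @param model An `xtal_model`.
#' @param shift Length-3 translation in angstroms (orthogonal frame).
#' @export
translate_model <- function(model, shift) {
  a <- model$atoms
  a$x <- a$x + shift[1]; a$y <- a$y + shift[2]; a$z <- a$z + shift[3]
  structure_model(model$cell, model$spacegroup, a)
}

#' Apply a symmetry operation plus fractional shift to a whole model
#'
#' Coordinates are fractionalized, transformed by `R x + t + shift` and
#' orthogonalized back.
#'
#' @param model An `xtal_model`.
#' @param op A [symop()].
#' @param shift Additional fractional translation (default none).
#' @export
transform_model <- function(model, op, shift = c(0, 0, 0)) {
  a <- model$atoms
  if (nrow(a)) {
    fr <- fractionalize(model$cell, as.matrix(a[, c("x", "y", "z")]))
    fr <- apply_symop(op, fr) + matrix(shift, nrow(fr), 3, byrow = TRUE)
    xyz <- orthogonalize(model$cell, fr)
    a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
  }
  structure_model(model$cell, model$spacegroup, a)
}
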
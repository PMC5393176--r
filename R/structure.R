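# Core structure container -------------------------------------------------
#
# A structure is a flat atom table plus metadata. Residue identity is the
# author key (chain, seq number, insertion code); file order is preserved
# and is the only ordering the package ever uses.

#' Construct a structure object from an atom table
#'
#' Low-level constructor used by the readers and the fixture generator.
#' Most users will obtain structures from [read_structure()] or
#' [build_duplex()].
#'
#' @param atoms data.frame with columns `chain`, `resno`, `icode`,
#'   `resname`, `name` (atom name, PDB convention), `element`, `x`, `y`,
#'   `z`, `occ`, `b`, `het` (logical, HETATM record).
#' @param id label for the structure.
#' @param source_format `"PDB"`, `"mmCIF"` or `"synthetic"`.
#' @return An object of class `rna_structure`.
#' @export
rna_structure <- function(atoms, id = "structure", source_format = "synthetic") {
  needed <- c("chain", "resno", "icode", "resname", "name", "element",
              "x", "y", "z", "occ", "b", "het")
  missing_cols <- setdiff(needed, names(atoms))
  if (length(missing_cols) > 0) {
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(atoms) == 0) stop("empty structure: no atoms")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("non-finite coordinates in atom table")
  }
  atoms$is_h <- is_hydrogen_name(atoms$name, atoms$element)
  atoms$key <- res_key(atoms$chain, atoms$resno, atoms$icode)
  rownames(atoms) <- NULL
  obj <- list(id = id, atoms = atoms, source_format = source_format)
  class(obj) <- "rna_structure"
  obj
}

#' @export
print.rna_structure <- function(x, ...) {
  ri <- residue_table(x)
  cat(sprintf("<rna_structure '%s'> %d atoms, %d residues (%d nucleotides), chains: %s [%s]\n",
              x$id, nrow(x$atoms), nrow(ri), sum(ri$is_nt),
              paste(unique(ri$chain), collapse = ","), x$source_format))
  invisible(x)
}

# Residue key: "chain:resno" or "chain:resno^icode"
res_key <- function(chain, resno, icode) {
  ic <- ifelse(is.na(icode) | icode == "" | icode == " ", "", paste0("^", icode))
  paste0(chain, ":", resno, ic)
}

# Mapping of residue names to a canonical parent. Covers standard
# ribonucleotides, deoxy forms and a small set of common modifications;
# everything else maps to NA and is excluded from nucleotide metrics.
PARENT_TABLE <- c(
  A = "A", G = "G", C = "C", U = "U",
  DA = "A", DG = "G", DC = "C", DT = "U", DU = "U",
  PSU = "U", H2U = "U", "4SU" = "U", "5MU" = "U", UR3 = "U", OMU = "U",
  "1MA" = "A", "2MA" = "A", MIA = "A", OMA = "A", A23 = "A",
  "5MC" = "C", OMC = "C", "4OC" = "C",
  "1MG" = "G", "2MG" = "G", M2G = "G", "7MG" = "G", OMG = "G", YG = "G",
  I = "G"
)

standard_parent <- function(resname) {
  out <- unname(PARENT_TABLE[toupper(resname)])
  out
}

is_hydrogen_name <- function(name, element = NULL) {
  if (!is.null(element)) {
    el <- toupper(trimws(element))
    known <- el %in% c("H", "D")
    has_el <- !is.na(el) & el != ""
    out <- ifelse(has_el, known, NA)
  } else {
    out <- rep(NA, length(name))
  }
  # fall back to the name: strip leading digits, first letter H
  stripped <- sub("^[0-9]+", "", name)
  by_name <- substr(stripped, 1, 1) %in% c("H", "D")
  ifelse(is.na(out), by_name, out)
}

#' Residue-level view of a structure
#'
#' @param structure an `rna_structure`.
#' @return data.frame, one row per residue in file order, with columns
#'   `key`, `chain`, `resno`, `icode`, `resname`, `parent` (canonical base
#'   or NA) and `is_nt`.
#' @export
residue_table <- function(structure) {
  at <- structure$atoms
  first <- !duplicated(at$key)
  ri <- data.frame(
    key = at$key[first], chain = at$chain[first], resno = at$resno[first],
    icode = at$icode[first], resname = at$resname[first],
    stringsAsFactors = FALSE
  )
  ri$parent <- standard_parent(ri$resname)
  ri$is_nt <- !is.na(ri$parent) & ri$parent %in% c("A", "C", "G", "U")
  ri
}

# atoms of one residue (by key), as a data.frame
residue_atoms <- function(structure, key) {
  structure$atoms[structure$atoms$key == key, , drop = FALSE]
}

# coordinates as an n x 3 matrix
coord_matrix <- function(atoms) {
  cbind(atoms$x, atoms$y, atoms$z)
}

#' Restrict a structure to a subset of residues
#'
#' @param structure an `rna_structure`.
#' @param keys residue keys to keep (order preserved from the file).
#' @return a new `rna_structure`.
#' @export
subset_residues <- function(structure, keys) {
  at <- structure$atoms[structure$atoms$key %in% keys, , drop = FALSE]
  if (nrow(at) == 0) stop("subset_residues: no atoms left")
  rna_structure(at[, setdiff(names(at), c("is_h", "key"))],
                id = structure$id, source_format = structure$source_format)
}

# Keep only residues that are standard-parent nucleotides
nucleotide_only <- function(structure) {
  ri <- residue_table(structure)
  subset_residues(structure, ri$key[ri$is_nt])
}

#' Apply a rigid-body transform to a structure
#'
#' @param structure an `rna_structure`.
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 numeric.
#' @return transformed `rna_structure`.
#' @export
transform_structure <- function(structure, rotation = diag(3),
                                translation = c(0, 0, 0)) {
  xyz <- coord_matrix(structure$atoms) %*% t(rotation)
  structure$atoms$x <- xyz[, 1] + translation[1]
  structure$atoms$y <- xyz[, 2] + translation[2]
  structure$atoms$z <- xyz[, 3] + translation[3]
  structure
}
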
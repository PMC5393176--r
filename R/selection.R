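# Canonical atom selections ------------------------------------------------
#
# Fixed name tables so that paired selections from two structures align
# positionally after intersecting on atom name.

BACKBONE_ATOMS <- c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "C3'", "O3'")
RIBOSE_ATOMS <- c("C1'", "C2'", "C3'", "C4'", "O4'", "O2'")
BASE_RING_ATOMS <- list(
  A = c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4"),
  G = c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4"),
  C = c("N1", "C2", "N3", "C4", "C5", "C6"),
  U = c("N1", "C2", "N3", "C4", "C5", "C6")
)
# full heavy base (ring + exocyclic)
BASE_ATOMS <- list(
  A = c(BASE_RING_ATOMS$A, "N6"),
  G = c(BASE_RING_ATOMS$G, "O6", "N2"),
  C = c(BASE_RING_ATOMS$C, "O2", "N4"),
  U = c(BASE_RING_ATOMS$U, "O2", "O4")
)

#' Select atoms of a residue by named subset
#'
#' Missing atoms are silently omitted; the returned rows follow a fixed
#' canonical name order so that equal selections from two residues align
#' positionally.
#'
#' @param residue data.frame of one residue's atoms (as returned by the
#'   internal accessor, or a subset of `structure$atoms`).
#' @param selection one of `"heavy"`, `"backbone"`, `"base"`, `"ribose"`,
#'   `"all"`.
#' @return data.frame of selected atom rows (possibly empty).
#' @export
select_atoms <- function(residue,
                         selection = c("heavy", "backbone", "base", "ribose", "all")) {
  selection <- match.arg(selection)
  if (selection == "all") return(residue)
  hy <- is_hydrogen_name(residue$name, residue$element)
  heavy <- residue[!hy, , drop = FALSE]
  if (selection == "heavy") return(heavy)
  parent <- standard_parent(residue$resname[1])
  wanted <- switch(selection,
    backbone = BACKBONE_ATOMS,
    ribose = RIBOSE_ATOMS,
    base = if (!is.na(parent) && parent %in% names(BASE_RING_ATOMS))
      BASE_RING_ATOMS[[parent]] else character(0)
  )
  idx <- match(wanted, heavy$name)
  heavy[idx[!is.na(idx)], , drop = FALSE]
}
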
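# Steric clash detection and clash score -----------------------------------
#
# Desk-scale approximation of the MolProbity quantity: heavy atoms only,
# no hydrogen placement, fixed van der Waals radii, 0.4 A overlap
# threshold. Reported clash scores are therefore comparable between models
# assessed here but not numerically to MolProbity output.

VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, P = 1.80, S = 1.80)
DEFAULT_VDW <- 1.70

# intra-residue heavy-atom connectivity of standard nucleotides
NT_BONDS <- list(
  c("P", "OP1"), c("P", "OP2"), c("P", "O5'"), c("O5'", "C5'"),
  c("C5'", "C4'"), c("C4'", "O4'"), c("C4'", "C3'"), c("C3'", "O3'"),
  c("C3'", "C2'"), c("C2'", "O2'"), c("C2'", "C1'"), c("O4'", "C1'"),
  c("C1'", "N9"), c("C1'", "N1"),
  # purine
  c("N9", "C8"), c("C8", "N7"), c("N7", "C5"), c("C5", "C6"),
  c("C6", "N1"), c("N1", "C2"), c("C2", "N3"), c("N3", "C4"),
  c("C4", "N9"), c("C4", "C5"), c("C6", "N6"), c("C6", "O6"),
  c("C2", "N2"),
  # pyrimidine
  c("C2", "O2"), c("N3", "C4"), c("C4", "N4"), c("C4", "O4"),
  c("C4", "C5"), c("C5", "C6"), c("C6", "N1")
)

vdw_radius <- function(element, name) {
  el <- toupper(ifelse(element == "" | is.na(element),
                       substr(sub("^[0-9]+", "", name), 1, 1), element))
  r <- VDW_RADII[el]
  ifelse(is.na(r), DEFAULT_VDW, r)
}

# bond adjacency over heavy atoms: nucleotide connectivity table, the
# inter-residue O3'-P link, and a generic distance fallback (< 1.8 A)
bond_list <- function(at) {
  n <- nrow(at)
  key_atom <- paste(at$key, at$name)
  bonds_i <- integer(0); bonds_j <- integer(0)
  add <- function(i, j) {
    bonds_i <<- c(bonds_i, pmin(i, j)); bonds_j <<- c(bonds_j, pmax(i, j))
  }
  # table bonds within residues
  for (k in unique(at$key)) {
    rows <- which(at$key == k)
    nm <- at$name[rows]
    for (b in NT_BONDS) {
      i <- rows[match(b[1], nm)]; j <- rows[match(b[2], nm)]
      if (!is.na(i) && !is.na(j)) add(i, j)
    }
  }
  # inter-residue O3'(i) - P(i+1) along each chain in file order
  keys <- unique(at$key)
  for (q in seq_len(length(keys) - 1)) {
    i <- which(at$key == keys[q] & at$name == "O3'")
    j <- which(at$key == keys[q + 1] & at$name == "P")
    if (length(i) == 1 && length(j) == 1 &&
        at$chain[i] == at$chain[j]) {
      d <- sqrt((at$x[i] - at$x[j])^2 + (at$y[i] - at$y[j])^2 +
                (at$z[i] - at$z[j])^2)
      if (d < 2.5) add(i, j)
    }
  }
  # generic fallback for non-standard residues: anything < 1.8 A bonded
  cand <- neighbor_pairs(cbind(at$x, at$y, at$z), 1.8)
  if (nrow(cand) > 0) {
    add(cand[, 1], cand[, 2])
  }
  unique(cbind(bonds_i, bonds_j))
}

#' Find steric clashes
#'
#' A clash is a non-bonded heavy-atom pair whose van der Waals overlap
#' (r_a + r_b - distance) reaches `threshold`. Excluded: atom pairs within
#' three covalent bonds (1-2, 1-3 and 1-4; connectivity from the standard
#' nucleotide table, the O3'-P backbone link, and a generic < 1.8 A
#' fallback -- 1-4 exclusion is required because para ring atoms and
#' backbone O3'(i)/C5'(i+1) sit at ~2.5-2.7 A in all correct RNA), and
#' hydrogen bonds: any base donor-acceptor heavy-atom pair within the
#' H-bond distance window (2.4-3.4 A), whether or not the residues form
#' an annotated base pair -- ideal helices carry genuine cross-strand
#' minor-groove H-bonds between unpaired residues.
#'
#' @param structure an `rna_structure`.
#' @param threshold overlap threshold in Angstrom (MolProbity convention
#'   0.4).
#' @return data.frame with `key_a`, `atom_a`, `key_b`, `atom_b`,
#'   `distance`, `overlap`.
#' @export
find_clashes <- function(structure, threshold = 0.4) {
  at <- structure$atoms[!structure$atoms$is_h, , drop = FALSE]
  n <- nrow(at)
  empty <- data.frame(key_a = character(0), atom_a = character(0),
                      key_b = character(0), atom_b = character(0),
                      distance = numeric(0), overlap = numeric(0),
                      stringsAsFactors = FALSE)
  if (n < 2) return(empty)
  radii <- vdw_radius(at$element, at$name)
  maxr <- max(radii)
  cand <- neighbor_pairs(cbind(at$x, at$y, at$z), 2 * maxr - threshold)
  if (nrow(cand) == 0) return(empty)
  # adjacency for bonded / 1-3 exclusion
  bonds <- bond_list(at)
  adj <- vector("list", n)
  for (r in seq_len(nrow(bonds))) {
    adj[[bonds[r, 1]]] <- c(adj[[bonds[r, 1]]], bonds[r, 2])
    adj[[bonds[r, 2]]] <- c(adj[[bonds[r, 2]]], bonds[r, 1])
  }
  bond_key <- paste(bonds[, 1], bonds[, 2])
  # H-bond exemption: base donor/acceptor role per atom
  ri <- residue_table(structure)
  parent_of <- ri$parent[match(at$key, ri$key)]
  is_donor <- is_acceptor <- rep(FALSE, n)
  for (p in c("A", "C", "G", "U")) {
    sel <- !is.na(parent_of) & parent_of == p
    is_donor[sel] <- at$name[sel] %in% BASE_DONORS[[p]]
    is_acceptor[sel] <- at$name[sel] %in% BASE_ACCEPTORS[[p]]
  }
  # the ribose 2'-OH donates (A-form O2'(i) -> O4'(i+1) is a genuine H-bond)
  nt <- !is.na(parent_of)
  is_donor[nt & at$name == "O2'"] <- TRUE
  is_acceptor[nt & at$name %in% c("O4'", "O2'")] <- TRUE
  d <- sqrt(rowSums((cbind(at$x, at$y, at$z)[cand[, 1], , drop = FALSE] -
                     cbind(at$x, at$y, at$z)[cand[, 2], , drop = FALSE])^2))
  overlap <- radii[cand[, 1]] + radii[cand[, 2]] - d
  keep <- overlap >= threshold
  rows <- which(keep)
  if (length(rows) == 0) return(empty)
  res <- list()
  for (r in rows) {
    i <- cand[r, 1]; j <- cand[r, 2]
    if (paste(i, j) %in% bond_key) next
    if (length(intersect(adj[[i]], adj[[j]])) > 0) next  # 1-3 pair
    # 1-4 pair: some neighbor of i bonded to some neighbor of j
    if (any(paste(pmin(rep(adj[[i]], each = length(adj[[j]])), adj[[j]]),
                  pmax(rep(adj[[i]], each = length(adj[[j]])), adj[[j]]))
            %in% bond_key)) next
    if (((is_donor[i] && is_acceptor[j]) || (is_acceptor[i] && is_donor[j])) &&
        d[r] >= 2.4 && d[r] <= 3.4) next                 # hydrogen bond
    res[[length(res) + 1]] <- data.frame(
      key_a = at$key[i], atom_a = at$name[i],
      key_b = at$key[j], atom_b = at$name[j],
      distance = d[r], overlap = overlap[r], stringsAsFactors = FALSE)
  }
  if (length(res) == 0) return(empty)
  do.call(rbind, res)
}

#' Clash score: clashes per 1000 heavy atoms
#'
#' @inheritParams find_clashes
#' @return list with `clashes` (data.frame), `n_atoms` and `score`
#'   (per 1000 atoms; NA for an empty structure).
#' @export
clash_score <- function(structure, threshold = 0.4) {
  heavy <- sum(!structure$atoms$is_h)
  cl <- find_clashes(structure, threshold)
  score <- if (heavy == 0) NA_real_ else 1000 * nrow(cl) / heavy
  list(clashes = cl, n_atoms = heavy, score = score)
}
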
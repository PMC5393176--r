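# Base-pair and stacking annotation ----------------------------------------
#
# Purely geometric Leontis-Westhof style annotation. Large-scale
# assessment relies on established annotation conventions; the thresholds
# here follow common practice and are overridable through
# `annotation_config()`.

# heavy-atom hydrogen-bond donors/acceptors on the base moiety
BASE_DONORS <- list(A = "N6", G = c("N1", "N2"), C = "N4", U = "N3")
BASE_ACCEPTORS <- list(A = c("N1", "N3", "N7"), G = c("O6", "N3", "N7"),
                       C = c("N3", "O2"), U = c("O2", "O4"))

# Leontis-Westhof edge membership (atoms may sit on two edges)
EDGE_ATOMS <- list(
  A = list(WC = c("N1", "C2", "N6"), Hoogsteen = c("N6", "N7", "C5"),
           Sugar = c("N3", "C2", "O2'")),
  G = list(WC = c("N1", "N2", "O6"), Hoogsteen = c("O6", "N7", "C5"),
           Sugar = c("N3", "N2", "O2'")),
  C = list(WC = c("N3", "N4", "O2"), Hoogsteen = c("N4", "C5", "C6"),
           Sugar = c("O2", "O2'")),
  U = list(WC = c("N3", "O4", "O2"), Hoogsteen = c("O4", "C5", "C6"),
           Sugar = c("O2", "O2'"))
)

#' Annotation thresholds
#'
#' All distances in Angstrom, angles in degrees. Defaults follow common
#' geometric annotation practice.
#'
#' @param pair_gate centroid-distance candidate gate for base pairs.
#' @param hbond_range heavy donor-acceptor distance window.
#' @param hbond_plane_max maximum out-of-plane component of a counted
#'   donor-acceptor contact (projection of the contact vector on the mean
#'   base normal); hydrogen bonds between paired bases are in-plane,
#'   vertical polar-atom contacts between stacked bases are not.
#' @param min_hbonds minimum inter-base donor-acceptor contacts.
#' @param plane_angle_max pair accepted when the base-plane angle is below
#'   this or above 180 minus this.
#' @param pair_vsep_max maximum vertical separation for a pair.
#' @param stack_gate centroid-distance gate for stacking.
#' @param stack_plane_angle_max maximum angle between stacked base normals
#'   (or from antiparallel).
#' @param stack_vsep vertical-separation window for stacking.
#' @param stack_hoffset_max maximum horizontal centroid offset for stacking.
#' @param strict_wc if TRUE, G-U wobbles are counted as non-Watson-Crick.
#' @return named list of thresholds.
#' @export
annotation_config <- function(pair_gate = 6.5, hbond_range = c(2.4, 3.4),
                              hbond_plane_max = 1.5,
                              min_hbonds = 2, plane_angle_max = 65,
                              pair_vsep_max = 2.5, stack_gate = 5.5,
                              stack_plane_angle_max = 30,
                              stack_vsep = c(2.0, 4.5),
                              stack_hoffset_max = 2.5,
                              strict_wc = FALSE) {
  as.list(environment())
}

#' Base reference frame of a nucleotide
#'
#' Least-squares plane through the base ring atoms. The origin is the
#' unweighted ring centroid; the normal is oriented by the right-hand rule
#' around the canonical ring atom order; the glycosidic vector points from
#' C1' to N9/N1.
#'
#' @param residue one residue's atom data.frame.
#' @return list with `origin`, `normal` (unit), `glycosidic` (unit), or
#'   `NULL` when fewer than 5 ring atoms are present (frame undefined).
#' @export
base_frame <- function(residue) {
  parent <- standard_parent(residue$resname[1])
  if (is.na(parent)) return(NULL)
  ring_names <- BASE_RING_ATOMS[[parent]]
  idx <- match(ring_names, residue$name)
  idx <- idx[!is.na(idx)]
  if (length(idx) < 5) return(NULL)
  xyz <- coord_matrix(residue[idx, ])
  origin <- colMeans(xyz)
  centered <- sweep(xyz, 2, origin)
  normal <- svd(centered)$v[, 3]
  # orient by ring atom order (right-hand rule over consecutive cross terms)
  k <- nrow(centered)
  cr <- c(0, 0, 0)
  for (i in seq_len(k)) {
    a <- centered[i, ]; b <- centered[if (i == k) 1 else i + 1, ]
    cr <- cr + c(a[2] * b[3] - a[3] * b[2],
                 a[3] * b[1] - a[1] * b[3],
                 a[1] * b[2] - a[2] * b[1])
  }
  if (sum(cr * normal) < 0) normal <- -normal
  n_name <- if (parent %in% c("A", "G")) "N9" else "N1"
  c1 <- which(residue$name == "C1'"); nn <- which(residue$name == n_name)
  glyc <- NULL
  if (length(c1) == 1 && length(nn) == 1) {
    v <- c(residue$x[nn] - residue$x[c1], residue$y[nn] - residue$y[c1],
           residue$z[nn] - residue$z[c1])
    glyc <- v / sqrt(sum(v^2))
  }
  list(origin = origin, normal = normal / sqrt(sum(normal^2)),
       glycosidic = glyc, parent = parent)
}

# frames for every nucleotide with a defined base; returns list keyed by
# residue key plus the key vector in file order
all_base_frames <- function(structure) {
  ri <- residue_table(structure)
  nt <- ri[ri$is_nt, , drop = FALSE]
  frames <- list()
  for (k in nt$key) {
    fr <- base_frame(residue_atoms(structure, k))
    if (!is.null(fr)) frames[[k]] <- fr
  }
  frames
}

#' Detect base pairs
#'
#' Residues i, j are paired when all of the following hold: base-centroid
#' distance within the gate; at least `min_hbonds` inter-base
#' donor-acceptor heavy-atom contacts inside the H-bond window; base-plane
#' angle near parallel or antiparallel; vertical separation (centroid
#' offset projected on the mean normal) within bound. Edges are assigned
#' per side by majority membership of the contacting atoms in the fixed
#' Watson-Crick / Hoogsteen / Sugar atom tables (ties broken
#' WC > Hoogsteen > Sugar); orientation is cis when the two glycosidic
#' vectors fall on the same side of the pair axis.
#'
#' @param structure an `rna_structure`.
#' @param config an [annotation_config()].
#' @return data.frame with columns `i`, `j` (residue keys, file order
#'   i < j), `edge_i`, `edge_j`, `orientation`, `n_hbonds`,
#'   `is_canonical`.
#' @export
detect_base_pairs <- function(structure, config = annotation_config()) {
  frames <- all_base_frames(structure)
  keys <- names(frames)
  empty <- data.frame(i = character(0), j = character(0),
                      edge_i = character(0), edge_j = character(0),
                      orientation = character(0), n_hbonds = integer(0),
                      is_canonical = logical(0), stringsAsFactors = FALSE)
  if (length(keys) < 2) return(empty)
  cents <- t(vapply(frames, function(f) f$origin, numeric(3)))
  cand <- neighbor_pairs(cents, config$pair_gate)
  if (nrow(cand) == 0) return(empty)
  at <- structure$atoms
  rows <- list()
  for (r in seq_len(nrow(cand))) {
    ki <- keys[cand[r, 1]]; kj <- keys[cand[r, 2]]
    fi <- frames[[ki]]; fj <- frames[[kj]]
    nbar <- mean_normal(fi$normal, fj$normal)
    hb <- hbond_contacts(at, ki, kj, fi$parent, fj$parent, config$hbond_range,
                         nbar, config$hbond_plane_max)
    if (nrow(hb) < config$min_hbonds) next
    pa <- plane_angle(fi$normal, fj$normal)
    if (pa > config$plane_angle_max && pa < 180 - config$plane_angle_max) next
    off <- fj$origin - fi$origin
    if (abs(sum(off * nbar)) > config$pair_vsep_max) next
    edge_i <- assign_edge(fi$parent, hb$atom_i)
    edge_j <- assign_edge(fj$parent, hb$atom_j)
    ori <- pair_orientation(fi, fj, nbar)
    canon <- edge_i == "WC" && edge_j == "WC" && ori == "cis" &&
      paste0(fi$parent, fj$parent) %in%
        c("AU", "UA", "GC", "CG", "GU", "UG")
    rows[[length(rows) + 1]] <- data.frame(
      i = ki, j = kj, edge_i = edge_i, edge_j = edge_j, orientation = ori,
      n_hbonds = nrow(hb), is_canonical = canon, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  # order by file order of i then j
  order_key <- match(out$i, keys) * (length(keys) + 1) + match(out$j, keys)
  out <- out[order(order_key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

hbond_contacts <- function(at, ki, kj, pi, pj, range, nbar = NULL,
                           plane_max = Inf) {
  ai <- at[at$key == ki, ]; aj <- at[at$key == kj, ]
  di <- ai[ai$name %in% BASE_DONORS[[pi]], ]
  ci <- ai[ai$name %in% BASE_ACCEPTORS[[pi]], ]
  dj <- aj[aj$name %in% BASE_DONORS[[pj]], ]
  cj <- aj[aj$name %in% BASE_ACCEPTORS[[pj]], ]
  res <- list()
  pair_block <- function(a, b) {
    if (nrow(a) == 0 || nrow(b) == 0) return(NULL)
    g <- expand.grid(u = seq_len(nrow(a)), v = seq_len(nrow(b)))
    dx <- a$x[g$u] - b$x[g$v]; dy <- a$y[g$u] - b$y[g$v]
    dz <- a$z[g$u] - b$z[g$v]
    d <- sqrt(dx^2 + dy^2 + dz^2)
    keep <- d >= range[1] & d <= range[2]
    if (!is.null(nbar) && is.finite(plane_max)) {
      keep <- keep &
        abs(dx * nbar[1] + dy * nbar[2] + dz * nbar[3]) <= plane_max
    }
    if (!any(keep)) return(NULL)
    data.frame(atom_i = a$name[g$u[keep]], atom_j = b$name[g$v[keep]],
               dist = d[keep], stringsAsFactors = FALSE)
  }
  r1 <- pair_block(di, cj)
  r2 <- pair_block(ci, dj)
  if (!is.null(r2)) {
    # r2 has i-side acceptors in column 1 already (atom_i names from ci)
    r2 <- data.frame(atom_i = r2$atom_i, atom_j = r2$atom_j, dist = r2$dist,
                     stringsAsFactors = FALSE)
  }
  out <- rbind(r1, r2)
  if (is.null(out)) data.frame(atom_i = character(0), atom_j = character(0),
                               dist = numeric(0)) else out
}

plane_angle <- function(n1, n2) {
  acos(max(-1, min(1, sum(n1 * n2)))) * 180 / pi
}

mean_normal <- function(n1, n2) {
  if (sum(n1 * n2) < 0) n2 <- -n2
  v <- n1 + n2
  v / sqrt(sum(v^2))
}

assign_edge <- function(parent, contact_atoms) {
  tab <- EDGE_ATOMS[[parent]]
  votes <- vapply(tab, function(a) sum(contact_atoms %in% a), numeric(1))
  # ties broken WC > Hoogsteen > Sugar (list order)
  names(tab)[which.max(votes)]
}

pair_orientation <- function(fi, fj, nbar) {
  if (is.null(fi$glycosidic) || is.null(fj$glycosidic)) return("cis")
  axis <- fj$origin - fi$origin
  axis <- axis / sqrt(sum(axis^2))
  perp <- c(nbar[2] * axis[3] - nbar[3] * axis[2],
            nbar[3] * axis[1] - nbar[1] * axis[3],
            nbar[1] * axis[2] - nbar[2] * axis[1])
  si <- sign(sum(fi$glycosidic * perp))
  sj <- sign(sum(fj$glycosidic * perp))
  if (si * sj >= 0) "cis" else "trans"
}

#' Detect base stacking
#'
#' Residues stack when their base centroids are close, their planes are
#' near parallel (or antiparallel), the vertical separation lies in the
#' stacking window and the horizontal centroid offset is small; pairs that
#' are already hydrogen-bonded base pairs are excluded.
#'
#' @inheritParams detect_base_pairs
#' @param pairs optional precomputed [detect_base_pairs()] result.
#' @return data.frame with columns `i`, `j` (residue keys, i < j in file
#'   order).
#' @export
detect_stacking <- function(structure, config = annotation_config(),
                            pairs = NULL) {
  frames <- all_base_frames(structure)
  keys <- names(frames)
  empty <- data.frame(i = character(0), j = character(0),
                      stringsAsFactors = FALSE)
  if (length(keys) < 2) return(empty)
  if (is.null(pairs)) pairs <- detect_base_pairs(structure, config)
  paired <- paste(pairs$i, pairs$j)
  cents <- t(vapply(frames, function(f) f$origin, numeric(3)))
  cand <- neighbor_pairs(cents, config$stack_gate)
  rows <- list()
  for (r in seq_len(nrow(cand))) {
    ki <- keys[cand[r, 1]]; kj <- keys[cand[r, 2]]
    if (paste(ki, kj) %in% paired) next
    fi <- frames[[ki]]; fj <- frames[[kj]]
    pa <- plane_angle(fi$normal, fj$normal)
    if (pa > config$stack_plane_angle_max &&
        pa < 180 - config$stack_plane_angle_max) next
    nbar <- mean_normal(fi$normal, fj$normal)
    off <- fj$origin - fi$origin
    vs <- abs(sum(off * nbar))
    if (vs < config$stack_vsep[1] || vs > config$stack_vsep[2]) next
    hoff2 <- sum(off^2) - vs^2
    if (hoff2 > config$stack_hoffset_max^2) next
    rows[[length(rows) + 1]] <- data.frame(i = ki, j = kj,
                                           stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  order_key <- match(out$i, keys) * (length(keys) + 1) + match(out$j, keys)
  out <- out[order(order_key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Interaction sets of a structure
#'
#' Partitions detected base pairs into the Watson-Crick set (cis WC/WC
#' pairs of A-U, G-C and, unless `strict_wc`, the G-U wobble) and the
#' non-Watson-Crick set (all other pairs), and attaches stacking pairs.
#'
#' @inheritParams detect_base_pairs
#' @return object of class `interaction_set`: list with data.frames
#'   `wc`, `nwc`, `stack`, `all`, each with residue-key columns `i`, `j`.
#' @export
interaction_sets <- function(structure, config = annotation_config()) {
  pairs <- detect_base_pairs(structure, config)
  stacks <- detect_stacking(structure, config, pairs = pairs)
  canon <- pairs$is_canonical
  if (config$strict_wc && nrow(pairs) > 0) {
    ri <- residue_table(structure)
    par <- function(k) ri$parent[match(k, ri$key)]
    wobble <- paste0(par(pairs$i), par(pairs$j)) %in% c("GU", "UG")
    canon <- canon & !wobble
  }
  structure(list(
    wc = pairs[canon, c("i", "j"), drop = FALSE],
    nwc = pairs[!canon, c("i", "j"), drop = FALSE],
    stack = stacks,
    all = pairs[, c("i", "j"), drop = FALSE],
    pairs = pairs
  ), class = "interaction_set")
}

#' @export
print.interaction_set <- function(x, ...) {
  cat(sprintf("<interaction_set> %d WC, %d non-WC, %d stacking\n",
              nrow(x$wc), nrow(x$nwc), nrow(x$stack)))
  invisible(x)
}

#' Export an annotation as tab-separated records
#'
#' @param structure an `rna_structure`.
#' @param path output path.
#' @param config an [annotation_config()].
#' @return `path`, invisibly.
#' @export
write_annotation <- function(structure, path, config = annotation_config()) {
  pairs <- detect_base_pairs(structure, config)
  utils::write.table(pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
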
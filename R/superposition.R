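# Rigid superposition, RMSD, DI, deformation profile -----------------------

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares optimal proper rotation and translation mapping `moving`
#' onto `fixed`. Reflections are corrected by flipping the sign of the
#' smallest singular vector, so the returned rotation always has
#' determinant +1.
#'
#' @param moving,fixed n x 3 coordinate matrices, n >= 3, rows paired.
#' @param weights optional non-negative per-point weights.
#' @return list with `rotation` (3x3), `translation` (length 3), `rmsd`
#'   and `n_atoms`. The transform maps moving points as
#'   `x %*% t(rotation) + translation`.
#' @export
kabsch_superpose <- function(moving, fixed, weights = NULL) {
  moving <- as.matrix(moving); fixed <- as.matrix(fixed)
  if (nrow(moving) != nrow(fixed)) {
    stop("kabsch_superpose: point counts differ (", nrow(moving), " vs ",
         nrow(fixed), ")")
  }
  n <- nrow(moving)
  if (n < 3) stop("kabsch_superpose: need at least 3 points, got ", n)
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0) || sum(weights) <= 0) {
    stop("kabsch_superpose: invalid weights")
  }
  w <- weights / sum(weights)
  cm <- colSums(moving * w); cf <- colSums(fixed * w)
  P <- sweep(moving, 2, cm); Q <- sweep(fixed, 2, cf)
  H <- t(P * w) %*% Q
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  translation <- cf - as.vector(R %*% cm)
  moved <- moving %*% t(R)
  moved <- sweep(moved, 2, translation, "+")
  rmsd <- sqrt(sum(w * rowSums((moved - fixed)^2)))
  list(rotation = R, translation = translation, rmsd = rmsd, n_atoms = n)
}

# Stack the common selected atoms of all mapped residue pairs.
# Returns list(model = matrix, ref = matrix, res_index = integer vector of
# mapping row per atom row).
paired_coordinates <- function(model, reference, mapping, selection = "heavy") {
  pm <- mapping$pairs
  m_list <- list(); r_list <- list(); idx <- list()
  for (k in seq_len(nrow(pm))) {
    ma <- select_atoms(residue_atoms(model, pm$model_key[k]), selection)
    ra <- select_atoms(residue_atoms(reference, pm$ref_key[k]), selection)
    common <- intersect(ma$name, ra$name)
    if (length(common) == 0) next
    m_list[[length(m_list) + 1]] <- coord_matrix(ma[match(common, ma$name), ])
    r_list[[length(r_list) + 1]] <- coord_matrix(ra[match(common, ra$name), ])
    idx[[length(idx) + 1]] <- rep(k, length(common))
  }
  if (length(m_list) == 0) {
    stop("no common atoms between model and reference; first divergent residue: ",
         pm$model_key[1])
  }
  list(model = do.call(rbind, m_list), ref = do.call(rbind, r_list),
       res_index = unlist(idx))
}

#' Global RMSD after one optimal superposition
#'
#' Superposes the model onto the reference once, over all common selected
#' atoms of all mapped residue pairs, and reports the RMSD over those same
#' atoms (Angstrom).
#'
#' @param model,reference `rna_structure` objects.
#' @param mapping a [map_residues()] result.
#' @param selection atom subset, see [select_atoms()].
#' @return numeric RMSD in Angstrom.
#' @export
global_rmsd <- function(model, reference, mapping, selection = "heavy") {
  pc <- paired_coordinates(model, reference, mapping, selection)
  if (nrow(pc$model) < 3) stop("global_rmsd: fewer than 3 common atoms")
  kabsch_superpose(pc$model, pc$ref)$rmsd
}

#' Per-nucleotide deformation profile
#'
#' For each mapped residue i the model is superposed onto the reference
#' using residue i's own common heavy atoms; entry (i, j) is then the mean
#' distance over residue j's common heavy atoms under that local transform.
#' Rows whose local superposition is degenerate (< 3 common atoms) are
#' flagged and filled with NA.
#'
#' @inheritParams global_rmsd
#' @return object of class `dp_matrix`: list with `residue_keys`
#'   (reference keys), `values` (N x N matrix, Angstrom), `degenerate`
#'   (logical per row).
#' @export
deformation_profile <- function(model, reference, mapping, selection = "heavy") {
  pc <- paired_coordinates(model, reference, mapping, selection)
  n <- nrow(mapping$pairs)
  vals <- matrix(NA_real_, n, n)
  degen <- logical(n)
  split_m <- split.data.frame(pc$model, pc$res_index)
  split_r <- split.data.frame(pc$ref, pc$res_index)
  present <- as.integer(names(split_m))
  for (ii in seq_along(present)) {
    i <- present[ii]
    mi <- split_m[[ii]]; ri <- split_r[[ii]]
    if (nrow(mi) < 3) { degen[i] <- TRUE; next }
    sp <- kabsch_superpose(mi, ri)
    moved <- sweep(pc$model %*% t(sp$rotation), 2, sp$translation, "+")
    d <- sqrt(rowSums((moved - pc$ref)^2))
    vals[i, present] <- vapply(seq_along(present), function(jj) {
      mean(d[pc$res_index == present[jj]])
    }, numeric(1))
  }
  degen[setdiff(seq_len(n), present)] <- TRUE
  structure(list(residue_keys = mapping$pairs$ref_key, values = vals,
                 degenerate = degen),
            class = "dp_matrix")
}

#' @export
print.dp_matrix <- function(x, ...) {
  ok <- !x$degenerate
  cat(sprintf("<dp_matrix> %d residues (%d degenerate), mean %.3f A, max %.3f A\n",
              length(x$residue_keys), sum(x$degenerate),
              mean(x$values[ok, ok], na.rm = TRUE),
              max(x$values[ok, ok], na.rm = TRUE)))
  invisible(x)
}

#' Parse a domain definition list
#'
#' Domains are named residue-range sets, `list(P1 = c("A:2-9", "A:80-87"))`
#' with chain:start-end inclusive in author numbering, or plain vectors of
#' residue keys.
#'
#' @param spec named list of character vectors (ranges or keys).
#' @param structure structure whose residues the ranges refer to.
#' @return named list of residue-key character vectors.
#' @export
resolve_domains <- function(spec, structure) {
  ri <- residue_table(structure)
  lapply(spec, function(entries) {
    keys <- character(0)
    for (e in entries) {
      m <- regmatches(e, regexec("^([^:]+):(-?[0-9]+)-(-?[0-9]+)$", e))[[1]]
      if (length(m) == 4) {
        sel <- ri$chain == m[2] & ri$resno >= as.integer(m[3]) &
          ri$resno <= as.integer(m[4])
        keys <- c(keys, ri$key[sel])
      } else {
        keys <- c(keys, e)
      }
    }
    unique(keys)
  })
}

#' Aggregate a deformation profile over structural domains
#'
#' Minimum, maximum and mean DP over each ordered domain pair's submatrix,
#' including intra-domain (self) pairs. Degenerate rows/columns are
#' excluded.
#'
#' @param dp a [deformation_profile()] result.
#' @param domains named list of residue-key vectors (see
#'   [resolve_domains()]).
#' @return data.frame with columns `domain_a`, `domain_b`, `min`, `max`,
#'   `mean`, `n`.
#' @export
aggregate_dp <- function(dp, domains) {
  keys <- dp$residue_keys
  unknown <- setdiff(unlist(domains), keys)
  if (length(unknown) > 0) {
    stop("aggregate_dp: domain residues not in DP matrix: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  ok <- !dp$degenerate
  out <- list()
  for (a in names(domains)) for (b in names(domains)) {
    ia <- which(keys %in% domains[[a]] & ok)
    ib <- which(keys %in% domains[[b]] & ok)
    sub <- dp$values[ia, ib, drop = FALSE]
    sub <- sub[is.finite(sub)]
    out[[length(out) + 1]] <- data.frame(
      domain_a = a, domain_b = b,
      min = if (length(sub)) min(sub) else NA_real_,
      max = if (length(sub)) max(sub) else NA_real_,
      mean = if (length(sub)) mean(sub) else NA_real_,
      n = length(sub), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Deformation index
#'
#' DI = RMSD / INF(all). An undefined or zero INF yields `NA` (never an
#' error): zero INF means no interaction was reproduced, for which a
#' finite DI is meaningless.
#'
#' @param rmsd non-negative RMSD in Angstrom.
#' @param inf_all INF over all base pairs, in `[0, 1]` or `NA`.
#' @return DI in Angstrom, or `NA`.
#' @export
deformation_index <- function(rmsd, inf_all) {
  if (is.na(rmsd) || rmsd < 0) stop("deformation_index: rmsd must be >= 0")
  if (is.na(inf_all) || inf_all <= 0) return(NA_real_)
  rmsd / inf_all
}

#' Export a DP matrix as tab-separated text
#'
#' @param dp a [deformation_profile()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dp_matrix <- function(dp, path) {
  m <- dp$values
  rownames(m) <- colnames(m) <- dp$residue_keys
  utils::write.table(format(m, digits = 4), path, sep = "\t",
                     quote = FALSE, col.names = NA)
  invisible(path)
}
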
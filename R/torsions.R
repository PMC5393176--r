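# Backbone/glycosidic torsions and the MCQ score ---------------------------
#
# The seven standard nucleotide torsions:
#   alpha:   O3'(i-1) - P - O5' - C5'
#   beta:    P - O5' - C5' - C4'
#   gamma:   O5' - C5' - C4' - C3'
#   delta:   C5' - C4' - C3' - O3'
#   epsilon: C4' - C3' - O3' - P(i+1)
#   zeta:    C3' - O3' - P(i+1) - O5'(i+1)
#   chi:     O4' - C1' - N9 - C4 (purines) / O4' - C1' - N1 - C2 (pyrimidines)
# Angles are in degrees in (-180, 180]; an angle whose defining atoms are
# absent (chain termini, unresolved atoms) is NA.

TORSION_NAMES <- c("alpha", "beta", "gamma", "delta", "epsilon", "zeta", "chi")

# dihedral of four points (rows of a 4x3 matrix), degrees in (-180, 180];
# NA when degenerate (collinear frames)
dihedral_angle <- function(p) {
  b1 <- p[2, ] - p[1, ]; b2 <- p[3, ] - p[2, ]; b3 <- p[4, ] - p[3, ]
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  if (sum(n1^2) < 1e-12 || sum(n2^2) < 1e-12) return(NA_real_)
  b2n <- b2 / sqrt(sum(b2^2))
  cr <- c(n1[2] * n2[3] - n1[3] * n2[2],
          n1[3] * n2[1] - n1[1] * n2[3],
          n1[1] * n2[2] - n1[2] * n2[1])
  ang <- atan2(sum(cr * b2n), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Backbone and glycosidic torsion profile
#'
#' Computes the seven standard torsions for each requested nucleotide.
#' `alpha` is undefined at a 5' terminus, `epsilon`/`zeta` at a 3'
#' terminus; any angle with a missing defining atom is `NA`.
#'
#' @param structure an `rna_structure`.
#' @param keys residue keys to profile; default all nucleotides, in file
#'   order.
#' @return object of class `torsion_profile`: data.frame with column
#'   `key` plus one column per torsion (degrees, NA when undefined).
#' @export
torsions <- function(structure, keys = NULL) {
  ri <- residue_table(structure)
  nt <- ri[ri$is_nt, , drop = FALSE]
  if (is.null(keys)) keys <- nt$key
  at <- structure$atoms
  getp <- function(key, name) {
    row <- which(at$key == key & at$name == name)
    if (length(row) == 0) return(NULL)
    c(at$x[row[1]], at$y[row[1]], at$z[row[1]])
  }
  # previous/next residue along the same chain in file order
  nt_pos <- match(keys, nt$key)
  out <- data.frame(key = keys, stringsAsFactors = FALSE)
  for (tn in TORSION_NAMES) out[[tn]] <- NA_real_
  for (r in seq_along(keys)) {
    i <- nt_pos[r]
    if (is.na(i)) next
    key <- nt$key[i]
    prev_key <- if (i > 1 && nt$chain[i - 1] == nt$chain[i]) nt$key[i - 1] else NULL
    next_key <- if (i < nrow(nt) && nt$chain[i + 1] == nt$chain[i]) nt$key[i + 1] else NULL
    # chain break check: O3'(prev)-P distance must be bond-like
    if (!is.null(prev_key)) {
      o3p <- getp(prev_key, "O3'"); pp <- getp(key, "P")
      if (is.null(o3p) || is.null(pp) || sqrt(sum((o3p - pp)^2)) > 2.5) prev_key <- NULL
    }
    if (!is.null(next_key)) {
      o3 <- getp(key, "O3'"); pn <- getp(next_key, "P")
      if (is.null(o3) || is.null(pn) || sqrt(sum((o3 - pn)^2)) > 2.5) next_key <- NULL
    }
    quad <- function(defs) {
      pts <- lapply(defs, function(d) getp(d[[1]], d[[2]]))
      if (any(vapply(pts, is.null, TRUE))) return(NA_real_)
      dihedral_angle(do.call(rbind, pts))
    }
    K <- function(nm) list(key, nm)
    Pv <- function(nm) list(prev_key, nm)
    Nx <- function(nm) list(next_key, nm)
    if (!is.null(prev_key)) {
      out$alpha[r] <- quad(list(Pv("O3'"), K("P"), K("O5'"), K("C5'")))
    }
    out$beta[r]  <- quad(list(K("P"), K("O5'"), K("C5'"), K("C4'")))
    out$gamma[r] <- quad(list(K("O5'"), K("C5'"), K("C4'"), K("C3'")))
    out$delta[r] <- quad(list(K("C5'"), K("C4'"), K("C3'"), K("O3'")))
    if (!is.null(next_key)) {
      out$epsilon[r] <- quad(list(K("C4'"), K("C3'"), K("O3'"), Nx("P")))
      out$zeta[r]    <- quad(list(K("C3'"), K("O3'"), Nx("P"), Nx("O5'")))
    }
    parent <- nt$parent[i]
    if (parent %in% c("A", "G")) {
      out$chi[r] <- quad(list(K("O4'"), K("C1'"), K("N9"), K("C4")))
    } else {
      out$chi[r] <- quad(list(K("O4'"), K("C1'"), K("N1"), K("C2")))
    }
  }
  class(out) <- c("torsion_profile", "data.frame")
  out
}

#' Circular difference of two angles
#'
#' @param a,b angles in degrees (any branch).
#' @return difference in degrees, in `[0, 180]`; vectorized.
#' @export
circular_diff <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

#' Mean of circular quantities (MCQ) between two torsion profiles
#'
#' Over all angle slots where at least one side is defined: both defined
#' contribute their circular difference; exactly one defined contributes a
#' 180 degree penalty; both undefined are excluded. The result is the
#' circular mean of those differences, folded to `[0, 180]`.
#'
#' @param model,reference [torsions()] profiles over the same residues
#'   (matched by row order).
#' @return list with `mcq` (degrees, NA if no comparable slot),
#'   `n_compared`, `n_penalized`.
#' @export
mcq <- function(model, reference) {
  if (nrow(model) != nrow(reference)) {
    stop("mcq: profiles cover different numbers of residues")
  }
  am <- as.matrix(model[TORSION_NAMES])
  ar <- as.matrix(reference[TORSION_NAMES])
  both <- !is.na(am) & !is.na(ar)
  one <- xor(is.na(am), is.na(ar))
  d <- c(circular_diff(am[both], ar[both]), rep(180, sum(one)))
  if (length(d) == 0) {
    return(list(mcq = NA_real_, n_compared = 0L, n_penalized = 0L))
  }
  rad <- d * pi / 180
  m <- atan2(mean(sin(rad)), mean(cos(rad))) * 180 / pi
  if (m < 0) m <- m + 360
  if (m > 180) m <- 360 - m
  list(mcq = m, n_compared = length(d), n_penalized = sum(one))
}

#' Write a per-residue torsion table
#'
#' Tab-separated, degrees, `NA` for undefined angles.
#'
#' @param profile a [torsions()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_torsions <- function(profile, path) {
  utils::write.table(profile, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
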
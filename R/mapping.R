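# Residue correspondence between a model and a reference -------------------

#' Map model residues onto reference residues
#'
#' The `identifier` strategy matches residues on the author key
#' (chain, seq number, insertion code). The `alignment` strategy runs a
#' global (Needleman-Wunsch) alignment of the standard-parent sequences per
#' chain pair (match +1, mismatch -1, gap -2) and maps aligned, non-gap
#' columns. `auto` (the default) tries `identifier` first and falls back to
#' `alignment` when identifier coverage drops below 0.8 -- models usually
#' share the target numbering, but defensiveness is cheap.
#'
#' Only standard-parent nucleotides are mapped; reference residues that are
#' unresolved in the crystal are simply absent from the mapping.
#'
#' @param model,reference `rna_structure` objects.
#' @param strategy `"auto"`, `"identifier"` or `"alignment"`.
#' @param min_coverage mappings covering less than this fraction of the
#'   reference nucleotides raise an error (default 0.3; signals wrong chain
#'   pairing).
#' @return object of class `residue_mapping`: list with `pairs`
#'   (data.frame `model_key`, `ref_key`), `strategy`, `coverage`.
#' @export
map_residues <- function(model, reference,
                         strategy = c("auto", "identifier", "alignment"),
                         min_coverage = 0.3) {
  strategy <- match.arg(strategy)
  mi <- residue_table(model); mi <- mi[mi$is_nt, , drop = FALSE]
  ri <- residue_table(reference); ri <- ri[ri$is_nt, , drop = FALSE]
  if (nrow(mi) == 0 || nrow(ri) == 0) {
    stop("map_residues: both structures must contain at least one nucleotide")
  }
  used <- strategy
  if (strategy %in% c("auto", "identifier")) {
    pairs <- map_by_identifier(mi, ri)
    used <- "identifier"
    if (strategy == "auto" && nrow(pairs) / nrow(ri) < 0.8) {
      pairs <- map_by_alignment(mi, ri)
      used <- "alignment"
    }
  } else {
    pairs <- map_by_alignment(mi, ri)
  }
  coverage <- nrow(pairs) / nrow(ri)
  if (coverage < min_coverage) {
    stop(sprintf("map_residues: coverage %.2f below %.2f - wrong chain pairing?",
                 coverage, min_coverage))
  }
  structure(list(pairs = pairs, strategy = used, coverage = coverage),
            class = "residue_mapping")
}

#' @export
print.residue_mapping <- function(x, ...) {
  cat(sprintf("<residue_mapping> %d pairs, strategy=%s, coverage=%.3f\n",
              nrow(x$pairs), x$strategy, x$coverage))
  invisible(x)
}

map_by_identifier <- function(mi, ri) {
  common <- intersect(mi$key, ri$key)
  # keep only parent-consistent matches
  mp <- mi$parent[match(common, mi$key)]
  rp <- ri$parent[match(common, ri$key)]
  common <- common[mp == rp]
  # preserve reference file order
  common <- ri$key[ri$key %in% common]
  data.frame(model_key = common, ref_key = common, stringsAsFactors = FALSE)
}

map_by_alignment <- function(mi, ri) {
  out <- list()
  m_chains <- unique(mi$chain); r_chains <- unique(ri$chain)
  # chain pairing: by shared id when available, otherwise greedy by score
  if (all(r_chains %in% m_chains)) {
    pairing <- data.frame(m = r_chains, r = r_chains, stringsAsFactors = FALSE)
  } else {
    score <- matrix(0, length(m_chains), length(r_chains))
    for (i in seq_along(m_chains)) for (j in seq_along(r_chains)) {
      score[i, j] <- nw_align(mi$parent[mi$chain == m_chains[i]],
                              ri$parent[ri$chain == r_chains[j]])$score
    }
    pairing <- data.frame(m = character(0), r = character(0))
    repeat {
      if (all(!is.finite(score))) break
      ij <- arrayInd(which.max(score), dim(score))
      if (!is.finite(score[ij[1], ij[2]])) break
      pairing <- rbind(pairing, data.frame(m = m_chains[ij[1]], r = r_chains[ij[2]]))
      score[ij[1], ] <- -Inf; score[, ij[2]] <- -Inf
      if (nrow(pairing) == min(length(m_chains), length(r_chains))) break
    }
  }
  for (k in seq_len(nrow(pairing))) {
    ms <- mi[mi$chain == pairing$m[k], , drop = FALSE]
    rs <- ri[ri$chain == pairing$r[k], , drop = FALSE]
    if (nrow(ms) == 0 || nrow(rs) == 0) next
    al <- nw_align(ms$parent, rs$parent)
    keep <- !is.na(al$i) & !is.na(al$j)
    if (!any(keep)) next
    out[[k]] <- data.frame(model_key = ms$key[al$i[keep]],
                           ref_key = rs$key[al$j[keep]],
                           stringsAsFactors = FALSE)
  }
  if (length(out) == 0) return(data.frame(model_key = character(0),
                                          ref_key = character(0)))
  do.call(rbind, out)
}

# Global alignment with linear gap penalty; returns aligned index vectors
# (NA = gap) and the optimal score.
nw_align <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  n <- length(a); m <- length(b)
  S <- matrix(0, n + 1, m + 1)
  S[, 1] <- gap * (0:n); S[1, ] <- gap * (0:m)
  P <- matrix(0L, n + 1, m + 1)  # 1 diag, 2 up (gap in b), 3 left (gap in a)
  P[, 1] <- 2L; P[1, ] <- 3L; P[1, 1] <- 0L
  for (i in seq_len(n)) {
    sub <- ifelse(a[i] == b, match, mismatch)
    for (j in seq_len(m)) {
      d <- S[i, j] + sub[j]; u <- S[i, j + 1] + gap; l <- S[i + 1, j] + gap
      best <- max(d, u, l)
      S[i + 1, j + 1] <- best
      P[i + 1, j + 1] <- if (best == d) 1L else if (best == u) 2L else 3L
    }
  }
  i <- n + 1; j <- m + 1; ai <- integer(0); aj <- integer(0)
  while (i > 1 || j > 1) {
    p <- P[i, j]
    if (p == 1L) { ai <- c(i - 1L, ai); aj <- c(j - 1L, aj); i <- i - 1; j <- j - 1 }
    else if (p == 2L) { ai <- c(i - 1L, ai); aj <- c(NA, aj); i <- i - 1 }
    else { ai <- c(NA, ai); aj <- c(j - 1L, aj); j <- j - 1 }
  }
  # aligned columns where both present must be parent-identical to map
  keep_mismatch <- !is.na(ai) & !is.na(aj)
  mism <- keep_mismatch & a[ifelse(is.na(ai), 1, ai)] != b[ifelse(is.na(aj), 1, aj)]
  ai[mism] <- NA; aj[mism] <- NA
  list(i = ai, j = aj, score = S[n + 1, m + 1])
}
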
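# Cell-list neighbor search -------------------------------------------------
#
# Returns all unordered index pairs (i < j) with distance <= cutoff.
# Linear-time in practice; used as the candidate gate for base-pair,
# stacking and clash detection.

neighbor_pairs <- function(coords, cutoff) {
  n <- nrow(coords)
  if (n < 2) return(matrix(integer(0), ncol = 2))
  cell <- floor(sweep(coords, 2, apply(coords, 2, min)) / cutoff)
  key <- cell[, 1] + 1e4 * cell[, 2] + 1e8 * cell[, 3]
  buckets <- split(seq_len(n), key)
  cell_of <- cell
  # bucket lookup by offset cells
  bkey <- function(cl) cl[, 1] + 1e4 * cl[, 2] + 1e8 * cl[, 3]
  offsets <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  out_i <- integer(0); out_j <- integer(0)
  bucket_keys <- as.numeric(names(buckets))
  for (b in seq_along(buckets)) {
    idx <- buckets[[b]]
    base_cell <- cell_of[idx[1], , drop = FALSE]
    neigh_keys <- bkey(sweep(offsets, 2, as.numeric(base_cell), "+"))
    for (nk in neigh_keys) {
      pos <- match(nk, bucket_keys)
      if (is.na(pos) || pos < b) next
      jdx <- buckets[[pos]]
      if (pos == b) {
        if (length(idx) < 2) next
        cmb <- utils::combn(idx, 2)
        ii <- cmb[1, ]; jj <- cmb[2, ]
      } else {
        grid_ij <- expand.grid(i = idx, j = jdx)
        ii <- grid_ij$i; jj <- grid_ij$j
      }
      d2 <- rowSums((coords[ii, , drop = FALSE] - coords[jj, , drop = FALSE])^2)
      keep <- d2 <= cutoff^2
      out_i <- c(out_i, pmin(ii[keep], jj[keep]))
      out_j <- c(out_j, pmax(ii[keep], jj[keep]))
    }
  }
  unique(cbind(out_i, out_j))
}

# brute-force reference used in tests
neighbor_pairs_exhaustive <- function(coords, cutoff) {
  n <- nrow(coords)
  if (n < 2) return(matrix(integer(0), ncol = 2))
  cmb <- utils::combn(n, 2)
  d2 <- rowSums((coords[cmb[1, ], , drop = FALSE] -
                 coords[cmb[2, ], , drop = FALSE])^2)
  cbind(out_i = cmb[1, d2 <= cutoff^2], out_j = cmb[2, d2 <= cutoff^2])
}
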
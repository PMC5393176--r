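# Extended dot-bracket output ----------------------------------------------

#' Render base pairs as extended dot-bracket notation
#'
#' A maximal nested subset (greedy over pairs sorted by ascending opening
#' position, longest pair first on ties) is rendered with `()`; pairs
#' crossing that subset are rendered with `[]` (pseudoknot convention) and
#' second-level crossings with `{}`.
#'
#' @param pairs two-column matrix or data.frame of 1-based positions.
#' @param length sequence length.
#' @return single character string.
#' @export
to_dot_bracket <- function(pairs, length) {
  opens <- c("(", "[", "{"); closes <- c(")", "]", "}")
  out <- rep(".", length)
  if (is.null(pairs) || NROW(pairs) == 0) return(paste(out, collapse = ""))
  p <- cbind(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
  storage.mode(p) <- "integer"
  if (any(p < 1 | p > length)) stop("to_dot_bracket: position out of range")
  if (anyDuplicated(c(p))) stop("to_dot_bracket: position collision - pairs must form a matching")
  remaining <- p[order(p[, 1], -p[, 2]), , drop = FALSE]
  level <- 1
  while (nrow(remaining) > 0) {
    if (level > 3) stop("to_dot_bracket: more than 3 crossing levels")
    kept <- matrix(integer(0), ncol = 2)
    keep_rows <- logical(nrow(remaining))
    for (r in seq_len(nrow(remaining))) {
      a <- remaining[r, 1]; b <- remaining[r, 2]
      crosses <- FALSE
      if (nrow(kept) > 0) {
        crosses <- any((kept[, 1] < a & a < kept[, 2] & kept[, 2] < b) |
                       (a < kept[, 1] & kept[, 1] < b & b < kept[, 2]))
      }
      if (!crosses) {
        kept <- rbind(kept, remaining[r, , drop = FALSE])
        keep_rows[r] <- TRUE
      }
    }
    out[kept[, 1]] <- opens[level]
    out[kept[, 2]] <- closes[level]
    remaining <- remaining[!keep_rows, , drop = FALSE]
    level <- level + 1
  }
  paste(out, collapse = "")
}
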
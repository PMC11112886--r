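# Pairwise site-count machinery shared by the diversity and distance code.
#
# Sequences are reduced to the unambiguous alphabet {A,C,G,T}; gap and
# ambiguity characters make a column non-comparable for any pair involving
# them.  All n x n count matrices are obtained with indicator cross-products
# so the cost is a handful of BLAS calls rather than a pair loop.

# indicator matrices for one alignment matrix (rows = samples)
pair_indicators <- function(m) {
  lapply(c(A = "A", C = "C", G = "G", T = "T"),
         function(b) (m == b) * 1)
}

# comparable / match / transition counts for all sample pairs
# returns list of n x n matrices: comparable, matches, transitions,
# diffs (= comparable - matches), transversions
pair_counts <- function(m, cols = NULL) {
  ind <- pair_indicators(m)
  if (!is.null(cols)) ind <- lapply(ind, function(x) x[, cols, drop = FALSE])
  pair_counts_from_indicators(ind)
}

pair_counts_from_indicators <- function(ind) {
  valid <- ind$A + ind$C + ind$G + ind$T
  comparable <- tcrossprod(valid)
  matches <- tcrossprod(ind$A) + tcrossprod(ind$C) +
    tcrossprod(ind$G) + tcrossprod(ind$T)
  ag <- tcrossprod(ind$A, ind$G)
  ct <- tcrossprod(ind$C, ind$T)
  transitions <- ag + t(ag) + ct + t(ct)
  diffs <- comparable - matches
  list(comparable = comparable, matches = matches,
       transitions = transitions, transversions = diffs - transitions,
       diffs = diffs)
}
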
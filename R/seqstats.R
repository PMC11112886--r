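#' Site classification: variable and parsimony-informative columns
#'
#' Columns are classified on unambiguous bases (A/C/G/T) only: gaps and IUPAC
#' ambiguity codes are ignored, so a column whose variation involves only
#' gaps or ambiguities is not variable.  A column is *variable* when at least
#' two distinct bases occur, and *parsimony-informative* (PI) when at least
#' two distinct bases each occur in at least two rows.
#'
#' @param aln A [labeled_alignment()] with at least two rows.
#' @return List with integer counts `n_variable` and `n_pi`.
#' @export
site_classes <- function(aln) {
  m <- aln$matrix
  if (nrow(m) < 2L) stop("site classification needs at least two sequences")
  counts <- base_count_matrix(m)            # 4 x L
  present <- counts >= 1L
  twice <- counts >= 2L
  list(n_variable = sum(colSums(present) >= 2L),
       n_pi = sum(colSums(twice) >= 2L))
}

# per-column counts of A, C, G, T over rows (4 x L integer matrix)
base_count_matrix <- function(m) {
  rbind(A = colSums(m == "A"), C = colSums(m == "C"),
        G = colSums(m == "G"), T = colSums(m == "T"))
}

#' Haplotype count under site exclusion
#'
#' Every column containing a gap or ambiguity code in *any* row is excluded,
#' then the number of distinct row strings over the remaining columns is
#' returned (the "exclude sites with gaps" haplotype convention).  If all
#' columns are excluded the count is 1 and a warning is raised.
#'
#' @param aln A [labeled_alignment()].
#' @return Integer haplotype count.
#' @export
haplotype_count <- function(aln) {
  m <- aln$matrix
  if (nrow(m) < 1L) stop("empty alignment")
  clean <- colSums(matrix(m %in% c("A", "C", "G", "T"), nrow(m))) == nrow(m)
  if (!any(clean)) {
    warning("all columns contain gaps or ambiguities; haplotype count is 1")
    return(1L)
  }
  sub <- m[, clean, drop = FALSE]
  length(unique(apply(sub, 1L, paste, collapse = "")))
}

#' GC content of an alignment (or a column range)
#'
#' Computed as (#G + #C) / (#A + #C + #G + #T) pooled over all rows; gaps and
#' ambiguity codes contribute to neither numerator nor denominator.
#'
#' @param aln A [labeled_alignment()].
#' @param region Optional `c(start, end)` 1-based inclusive column range.
#' @return GC fraction in `[0, 1]`.
#' @export
gc_content <- function(aln, region = NULL) {
  m <- aln$matrix
  if (!is.null(region)) {
    stopifnot(length(region) == 2L, region[1L] >= 1L,
              region[2L] <= ncol(m), region[1L] <= region[2L])
    m <- m[, region[1L]:region[2L], drop = FALSE]
  }
  gc <- sum(m == "G" | m == "C")
  at <- sum(m == "A" | m == "T")
  if (gc + at == 0L) stop("region contains no unambiguous bases")
  gc / (gc + at)
}

#' Feature table across barcoding datasets
#'
#' One row per dataset with the aligned length, variable-site and
#' PI-site counts and percentages, haplotype count and GC content —
#' the standard feature comparison reported for candidate barcodes.
#' Percentages use two-decimal half-up rounding.
#'
#' @param alns List of [labeled_alignment()] objects.
#' @return Data frame with columns `dataset`, `aligned_length`, `n_variable`,
#'   `pct_variable`, `n_pi`, `pct_pi`, `n_haplotypes`, `gc_content`.
#' @export
features_table <- function(alns) {
  stopifnot(length(alns) >= 1L)
  rows <- lapply(alns, function(a) {
    sc <- site_classes(a)
    L <- aln_length(a)
    data.frame(
      dataset = a$name,
      aligned_length = L,
      n_variable = sc$n_variable,
      pct_variable = round_half_up(100 * sc$n_variable / L, 2L),
      n_pi = sc$n_pi,
      pct_pi = round_half_up(100 * sc$n_pi / L, 2L),
      n_haplotypes = haplotype_count(a),
      gc_content = gc_content(a),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# round() ties away from zero (half-up), unlike base R's banker's rounding
round_half_up <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
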
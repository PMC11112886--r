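#' Nucleotide diversity (pi)
#'
#' The average, over all sample pairs, of the proportion of differing sites
#' among the sites where both sequences carry an unambiguous base
#' (per-pair comparable-site denominators).  Pairs with no comparable sites
#' are skipped; if every pair is skipped an error is raised.
#'
#' @param aln A [labeled_alignment()] with at least two rows.
#' @param interval Optional `c(start, end)` 1-based inclusive column range.
#' @return Per-site nucleotide diversity (non-negative scalar).
#' @export
nucleotide_diversity <- function(aln, interval = NULL) {
  m <- aln$matrix
  if (nrow(m) < 2L) stop("nucleotide diversity needs at least two sequences")
  cols <- NULL
  if (!is.null(interval)) {
    stopifnot(interval[1L] >= 1L, interval[2L] <= ncol(m),
              interval[1L] <= interval[2L])
    cols <- interval[1L]:interval[2L]
  }
  pc <- pair_counts(m, cols)
  ut <- upper.tri(pc$comparable)
  comp <- pc$comparable[ut]
  usable <- comp > 0
  if (!any(usable)) stop("no sample pair has comparable sites in the interval")
  mean(pc$diffs[ut][usable] / comp[usable])
}

#' Sliding-window nucleotide diversity profile
#'
#' Windows start at columns 1, 1+step, 1+2*step, ... while the start lies
#' inside the alignment; a final window truncated by the alignment end is
#' retained but flagged `partial`.  If the window exceeds the alignment
#' length a single whole-alignment window is returned with a warning.
#'
#' @param aln A [labeled_alignment()].
#' @param window Window length in bp (default 600).
#' @param step Step size in bp (default 100).
#' @return A `window_profile`: list with `window`, `step` and a data frame
#'   `windows` (`start`, `end`, `midpoint`, `pi`, `partial`).
#' @export
sliding_window <- function(aln, window = 600L, step = 100L) {
  stopifnot(window >= step, step >= 1L)
  L <- aln_length(aln)
  if (window > L) {
    warning("window longer than alignment; using a single whole-alignment window")
    starts <- 1L
  } else {
    starts <- seq.int(1L, L, by = step)
  }
  ends <- pmin(starts + window - 1L, L)
  ind <- pair_indicators(aln$matrix)
  pi <- vapply(seq_along(starts), function(i) {
    pc <- pair_counts_from_indicators(
      lapply(ind, function(x) x[, starts[i]:ends[i], drop = FALSE]))
    ut <- upper.tri(pc$comparable)
    comp <- pc$comparable[ut]
    usable <- comp > 0
    if (!any(usable)) return(NA_real_)
    mean(pc$diffs[ut][usable] / comp[usable])
  }, numeric(1))
  windows <- data.frame(start = starts, end = ends,
                        midpoint = (starts + ends) / 2, pi = pi,
                        partial = (ends - starts + 1L) < window)
  structure(list(window = as.integer(window), step = as.integer(step),
                 aligned_length = L, windows = windows),
            class = "window_profile")
}

#' @export
print.window_profile <- function(x, ...) {
  cat("window_profile: ", nrow(x$windows), " windows (", x$window, "/",
      x$step, " bp) over ", x$aligned_length, " columns; max pi = ",
      signif(max(x$windows$pi, na.rm = TRUE), 4), "\n", sep = "")
  invisible(x)
}

#' Call hypervariable regions (divergence hotspots)
#'
#' A named region is a hotspot when the peak ("crest") window diversity
#' within it exceeds `pi_threshold` *and* its aligned length exceeds
#' `length_threshold`.  The peak is the maximum pi over complete (non-partial)
#' windows whose midpoint falls inside the region.  Output is sorted by peak
#' pi, descending.
#'
#' @param profile A `window_profile` from [sliding_window()].
#' @param annotations Data frame with columns `name`, `start`, `end`
#'   (1-based inclusive, non-overlapping).
#' @param pi_threshold Peak-diversity threshold (default 0.020).
#' @param length_threshold Minimum aligned region length in bp (default 600).
#' @return Data frame of hotspots: `region_name`, `start`, `end`,
#'   `aligned_length`, `peak_pi`.
#' @export
call_hotspots <- function(profile, annotations,
                          pi_threshold = 0.020, length_threshold = 600L) {
  empty <- data.frame(region_name = character(0), start = integer(0),
                      end = integer(0), aligned_length = integer(0),
                      peak_pi = numeric(0), stringsAsFactors = FALSE)
  if (is.null(annotations) || nrow(annotations) == 0L) return(empty)
  w <- profile$windows
  w <- w[!w$partial & !is.na(w$pi), , drop = FALSE]
  rows <- lapply(seq_len(nrow(annotations)), function(i) {
    a <- annotations[i, ]
    inside <- w$midpoint >= a$start & w$midpoint <= a$end
    peak <- if (any(inside)) max(w$pi[inside]) else NA_real_
    len <- a$end - a$start + 1L
    if (!is.na(peak) && peak > pi_threshold && len > length_threshold) {
      data.frame(region_name = a$name, start = a$start, end = a$end,
                 aligned_length = len, peak_pi = peak,
                 stringsAsFactors = FALSE)
    } else NULL
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty)
  out <- out[order(-out$peak_pi), , drop = FALSE]
  rownames(out) <- NULL
  out
}
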
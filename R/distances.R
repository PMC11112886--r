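#' Kimura 2-parameter distance between two aligned sequences
#'
#' With `P` and `Q` the transition (A<->G, C<->T) and transversion
#' proportions over comparable columns (both bases unambiguous),
#' `d = -1/2 * log(1 - 2P - Q) - 1/4 * log(1 - 2Q)`.
#'
#' @param seq_a,seq_b Character vectors of single characters, or strings, of
#'   equal length (rows of one alignment).
#' @return The K2P distance (non-negative scalar).  Saturated pairs
#'   (`1 - 2P - Q <= 0` or `1 - 2Q <= 0`) and pairs with no comparable
#'   columns are errors.
#' @export
k2p_distance <- function(seq_a, seq_b) {
  a <- if (length(seq_a) == 1L) strsplit(toupper(seq_a), "")[[1L]] else toupper(seq_a)
  b <- if (length(seq_b) == 1L) strsplit(toupper(seq_b), "")[[1L]] else toupper(seq_b)
  stopifnot(length(a) == length(b))
  bases <- c("A", "C", "G", "T")
  comp <- a %in% bases & b %in% bases
  n <- sum(comp)
  if (n == 0L) stop("no comparable columns between the two sequences")
  a <- a[comp]; b <- b[comp]
  ts <- sum((a == "A" & b == "G") | (a == "G" & b == "A") |
            (a == "C" & b == "T") | (a == "T" & b == "C"))
  diff <- sum(a != b)
  k2p_from_counts(ts, diff - ts, n)
}

k2p_from_counts <- function(ts, tv, n) {
  P <- ts / n
  Q <- tv / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    stop("K2P distance undefined (saturation): 1-2P-Q = ", signif(w1, 4),
         ", 1-2Q = ", signif(w2, 4))
  }
  -0.5 * log(w1) - 0.25 * log(w2)
}

#' Pairwise distance matrix over all samples of an alignment
#'
#' @param aln A [labeled_alignment()] with at least two rows.
#' @param model `"K2P"` for Kimura 2-parameter corrected distances or
#'   `"raw_differences"` for integer counts of differing comparable columns.
#' @param deletion `"pairwise"` (each pair uses its own comparable columns,
#'   the default) or `"complete"` (columns with any gap/ambiguity in any row
#'   are dropped for all pairs).
#' @return A `sample_dist` object: list with the symmetric `values` matrix
#'   (dimnames = sample ids), `model`, `deletion` and the `samples` table.
#'   Saturated K2P pairs raise an error naming the offending pair.
#' @export
distance_matrix <- function(aln, model = c("K2P", "raw_differences"),
                            deletion = c("pairwise", "complete")) {
  model <- match.arg(model)
  deletion <- match.arg(deletion)
  m <- aln$matrix
  if (nrow(m) < 2L) stop("distance matrix needs at least two sequences")
  cols <- NULL
  if (deletion == "complete") {
    keep <- colSums(matrix(m %in% c("A", "C", "G", "T"), nrow(m))) == nrow(m)
    if (!any(keep)) stop("complete deletion removed every column")
    cols <- which(keep)
  }
  pc <- pair_counts(m, cols)
  if (any(pc$comparable[upper.tri(pc$comparable)] == 0)) {
    bad <- which(pc$comparable == 0 & upper.tri(pc$comparable), arr.ind = TRUE)[1L, ]
    stop("no comparable columns between ", rownames(m)[bad[1L]], " and ",
         rownames(m)[bad[2L]])
  }
  if (model == "raw_differences") {
    d <- pc$diffs
  } else {
    P <- pc$transitions / pc$comparable
    Q <- pc$transversions / pc$comparable
    w1 <- 1 - 2 * P - Q
    w2 <- 1 - 2 * Q
    sat <- (w1 <= 0 | w2 <= 0) & upper.tri(w1)
    if (any(sat)) {
      bad <- which(sat, arr.ind = TRUE)[1L, ]
      stop("K2P distance undefined (saturation) for pair ",
           rownames(m)[bad[1L]], " / ", rownames(m)[bad[2L]])
    }
    d <- -0.5 * log(w1) - 0.25 * log(w2)
  }
  diag(d) <- 0
  dimnames(d) <- list(rownames(m), rownames(m))
  structure(list(values = d, model = model, deletion = deletion,
                 samples = aln$samples),
            class = "sample_dist")
}

#' @export
print.sample_dist <- function(x, ...) {
  cat("sample_dist (", x$model, ", ", x$deletion, " deletion): ",
      nrow(x$values), " samples\n", sep = "")
  invisible(x)
}

#' Barcoding-gap analysis per multi-individual species
#'
#' A species sampled with two or more individuals is successfully identified
#' by the distance method when its minimum interspecific distance is strictly
#' larger than its maximum intraspecific distance (ties count as failure).
#' Singleton species are not assessed but do act as potential nearest
#' neighbors.
#'
#' @param dm A `sample_dist` from [distance_matrix()].
#' @param samples Optional sample table (defaults to the one stored in `dm`).
#' @return Data frame with one row per multi-individual species: `species`,
#'   `n_individuals`, `max_intra`, `min_inter`, `nearest_other`, `has_gap`.
#'   Empty (with a warning) when no species has multiple individuals.
#' @export
barcoding_gaps <- function(dm, samples = NULL) {
  if (is.null(samples)) samples <- dm$samples
  d <- dm$values
  sp <- samples$species[match(rownames(d), samples$sample_id)]
  sizes <- table(sp)
  multi <- names(sizes)[sizes >= 2L]
  if (length(multi) == 0L) {
    warning("no species with multiple individuals; nothing to assess")
    return(data.frame(species = character(0), n_individuals = integer(0),
                      max_intra = numeric(0), min_inter = numeric(0),
                      nearest_other = character(0), has_gap = logical(0)))
  }
  rows <- lapply(multi, function(s) {
    inside <- sp == s
    intra <- d[inside, inside, drop = FALSE]
    max_intra <- max(intra[upper.tri(intra)])
    inter <- d[inside, !inside, drop = FALSE]
    min_inter <- min(inter)
    nn <- sp[!inside][which(inter == min_inter, arr.ind = TRUE)[1L, 2L]]
    data.frame(species = s, n_individuals = as.integer(sizes[[s]]),
               max_intra = max_intra, min_inter = min_inter,
               nearest_other = nn, has_gap = min_inter > max_intra,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Zero-K2P summary statistics
#'
#' `zero_k2p` counts the multi-individual species whose minimum
#' interspecific K2P distance is exactly zero (species that cannot show a
#' barcoding gap for lack of interspecific variation); `zero_k2p_all_pairs`
#' counts the unordered species pairs — over *all* species, singletons
#' included — whose minimum between-species distance is zero.
#'
#' @param dm A K2P `sample_dist`.
#' @param samples Optional sample table (defaults to the one stored in `dm`).
#' @return List with integer `zero_k2p` and `zero_k2p_all_pairs`.
#' @export
zero_k2p_stats <- function(dm, samples = NULL) {
  if (is.null(samples)) samples <- dm$samples
  if (dm$model != "K2P") stop("zero_k2p_stats needs a K2P distance matrix")
  d <- dm$values
  sp <- samples$species[match(rownames(d), samples$sample_id)]
  species <- unique(sp)
  # minimum between-species distance for every unordered species pair
  min_between <- matrix(NA_real_, length(species), length(species),
                        dimnames = list(species, species))
  for (i in seq_along(species)) {
    for (j in seq_len(i - 1L)) {
      block <- d[sp == species[i], sp == species[j], drop = FALSE]
      min_between[i, j] <- min(block)
    }
  }
  sizes <- table(sp)
  multi <- names(sizes)[sizes >= 2L]
  zero_k2p <- sum(vapply(multi, function(s) {
    k <- match(s, species)
    vals <- c(min_between[k, seq_len(k - 1L)],
              min_between[seq_along(species) > k, k])
    min(vals) == 0
  }, logical(1)))
  list(zero_k2p = as.integer(zero_k2p),
       zero_k2p_all_pairs = as.integer(sum(min_between == 0, na.rm = TRUE)))
}

#' AMID: average minimum interspecific difference
#'
#' For each multi-individual species, take the minimum raw-difference count
#' to any sample of another species; report the mean and range of those
#' minima.
#'
#' @param dm_raw A `sample_dist` with `model = "raw_differences"`.
#' @param samples Optional sample table (defaults to the one stored in `dm`).
#' @return List with `mean`, `min`, `max` over the per-species minima.
#' @export
amid <- function(dm_raw, samples = NULL) {
  if (is.null(samples)) samples <- dm_raw$samples
  if (dm_raw$model != "raw_differences") {
    stop("AMID is defined on raw-difference counts")
  }
  d <- dm_raw$values
  sp <- samples$species[match(rownames(d), samples$sample_id)]
  sizes <- table(sp)
  multi <- names(sizes)[sizes >= 2L]
  if (length(multi) == 0L) stop("no species with multiple individuals")
  minima <- vapply(multi, function(s) {
    min(d[sp == s, sp != s, drop = FALSE])
  }, numeric(1))
  list(mean = mean(minima), min = min(minima), max = max(minima))
}

#' Distance-based evaluation of one barcoding dataset
#'
#' Runs the full distance-based species-discrimination analysis: K2P
#' barcoding gaps and resolution, zero-K2P counts, and AMID on raw
#' differences.
#'
#' @param aln A [labeled_alignment()].
#' @param deletion Passed to [distance_matrix()].
#' @return A [discrimination_report()] whose species table holds the
#'   barcoding-gap rows and whose summary holds `resolution_pct`,
#'   `zero_k2p`, `zero_k2p_all_pairs`, `amid_mean`, `amid_min`, `amid_max`.
#' @export
evaluate_distance <- function(aln, deletion = "pairwise") {
  dm_k2p <- distance_matrix(aln, "K2P", deletion)
  dm_raw <- distance_matrix(aln, "raw_differences", deletion)
  gaps <- barcoding_gaps(dm_k2p)
  zk <- zero_k2p_stats(dm_k2p)
  am <- amid(dm_raw)
  species <- data.frame(
    species = gaps$species, n_individuals = gaps$n_individuals,
    success = gaps$has_gap, max_intra = gaps$max_intra,
    min_inter = gaps$min_inter, nearest_other = gaps$nearest_other,
    stringsAsFactors = FALSE
  )
  discrimination_report(aln$name, species, list(
    method = "distance",
    resolution_pct = round_half_up(100 * mean(gaps$has_gap), 2L),
    n_assessed = nrow(gaps), n_success = sum(gaps$has_gap),
    zero_k2p = zk$zero_k2p, zero_k2p_all_pairs = zk$zero_k2p_all_pairs,
    amid_mean = am$mean, amid_min = am$min, amid_max = am$max
  ))
}

#' Regression of species resolution on the number of zero-K2P species
#'
#' Ordinary least squares of dataset resolution percentage on the 0K2P
#' count, with the Pearson correlation and its two-sided p-value; used to
#' test whether lack of interspecific variation drives discrimination
#' failure across datasets.
#'
#' @param reports List of distance [discrimination_report()]s (>= 3), or a
#'   data frame with columns `resolution_pct` and `zero_k2p`.
#' @return List with `slope`, `intercept`, `r`, `p`.
#' @export
resolution_vs_zero_k2p <- function(reports) {
  if (is.data.frame(reports)) {
    df <- reports
  } else {
    df <- do.call(rbind, lapply(reports, function(r) {
      data.frame(resolution_pct = r$summary$resolution_pct,
                 zero_k2p = r$summary$zero_k2p)
    }))
  }
  if (nrow(df) < 3L) stop("need at least three datasets")
  if (stats::var(df$zero_k2p) == 0) stop("zero variance in the 0K2P counts")
  fit <- stats::lm(resolution_pct ~ zero_k2p, data = df)
  if (stats::var(df$resolution_pct) == 0) {
    r <- 0; p <- 1
  } else {
    ct <- stats::cor.test(df$zero_k2p, df$resolution_pct)
    r <- unname(ct$estimate); p <- ct$p.value
  }
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]), r = r, p = p)
}

#' Export a distance matrix as TSV
#'
#' @param dm A `sample_dist`.
#' @param path Output path.
#' @param format `"square"` for a full labeled matrix or `"lower"` for a
#'   PHYLIP-style lower triangle.
#' @export
write_distance_matrix <- function(dm, path, format = c("square", "lower")) {
  format <- match.arg(format)
  d <- dm$values
  if (format == "square") {
    df <- data.frame(sample_id = rownames(d), d, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(as.character(nrow(d)), con)
    for (i in seq_len(nrow(d))) {
      vals <- if (i == 1L) character(0) else
        sprintf("%.10g", d[i, seq_len(i - 1L)])
      writeLines(paste(c(rownames(d)[i], vals), collapse = "\t"), con)
    }
  }
  invisible(path)
}
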
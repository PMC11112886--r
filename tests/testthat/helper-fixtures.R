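# Fixture builders and independent brute-force oracles.  The oracles use
# plain per-column / per-pair loops over character vectors so they share no
# code path with the package's cross-product implementations.

BASES <- c("A", "C", "G", "T")

# random alignment with optional gaps/ambiguities; species assigned in
# blocks of `per_species` rows
rand_aln <- function(n = 6, L = 200, seed = 1, gap_frac = 0, amb_frac = 0,
                     per_species = 2, name = "rnd") {
  set.seed(seed)
  alphabet <- BASES
  m <- matrix(sample(alphabet, n * L, replace = TRUE), nrow = n)
  if (gap_frac > 0) m[sample(length(m), round(gap_frac * length(m)))] <- "-"
  if (amb_frac > 0) m[sample(length(m), round(amb_frac * length(m)))] <- "N"
  ids <- sprintf("s%02d", seq_len(n))
  rownames(m) <- ids
  sp <- sprintf("sp%02d", ceiling(seq_len(n) / per_species))
  labeled_alignment(m, data.frame(sample_id = ids, species = sp),
                    name = name)
}

# clustered alignment: per-species consensus sequences differ by
# `between` substitutions; individuals differ from their consensus by
# `within` substitutions (all at distinct positions, so counts are exact)
clustered_aln <- function(sizes, L = 300, between = 20, within = 2, seed = 1) {
  set.seed(seed)
  n_sp <- length(sizes)
  base <- sample(BASES, L, replace = TRUE)
  mutate_at <- function(seq, pos) {
    for (p in pos) seq[p] <- sample(setdiff(BASES, seq[p]), 1)
    seq
  }
  rows <- list()
  sp_labels <- character(0)
  pos_pool <- sample(L)
  used <- 0
  for (s in seq_len(n_sp)) {
    cons <- mutate_at(base, pos_pool[seq_len(between) + used])
    used <- used + between
    for (i in seq_len(sizes[s])) {
      pos <- pos_pool[seq_len(within) + used]
      used <- used + within
      rows[[length(rows) + 1]] <- mutate_at(cons, pos)
      sp_labels <- c(sp_labels, sprintf("sp%02d", s))
    }
  }
  m <- do.call(rbind, rows)
  ids <- sprintf("%s_%d", sp_labels, unlist(lapply(sizes, seq_len)))
  rownames(m) <- ids
  labeled_alignment(m, data.frame(sample_id = ids, species = sp_labels),
                    name = "clustered")
}

toy_map <- function(ids, species = NULL, section = "", provenance = "own") {
  if (is.null(species)) species <- toupper(substr(ids, 1, 1))
  data.frame(sample_id = ids, species = species, section = section,
             provenance = provenance, stringsAsFactors = FALSE)
}

write_toy_fasta <- function(seqs, path) {
  lines <- unlist(lapply(names(seqs), function(id) {
    c(paste0(">", id), seqs[[id]])
  }))
  writeLines(lines, path)
  path
}

write_toy_map <- function(map, path) {
  write.table(map, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

## ---- oracles -------------------------------------------------------------

oracle_site_classes <- function(m) {
  nv <- 0L; npi <- 0L
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    col <- col[col %in% BASES]
    tab <- table(col)
    if (sum(tab >= 1) >= 2) nv <- nv + 1L
    if (sum(tab >= 2) >= 2) npi <- npi + 1L
  }
  list(n_variable = nv, n_pi = npi)
}

oracle_haplotypes <- function(m) {
  keep <- apply(m, 2, function(col) all(col %in% BASES))
  if (!any(keep)) return(1L)
  length(unique(apply(m[, keep, drop = FALSE], 1, paste, collapse = "")))
}

oracle_pair_counts <- function(a, b) {
  comp <- a %in% BASES & b %in% BASES
  a <- a[comp]; b <- b[comp]
  ts <- 0L
  for (k in seq_along(a)) {
    if ((a[k] == "A" && b[k] == "G") || (a[k] == "G" && b[k] == "A") ||
        (a[k] == "C" && b[k] == "T") || (a[k] == "T" && b[k] == "C")) {
      ts <- ts + 1L
    }
  }
  list(n = length(a), diffs = sum(a != b), ts = ts)
}

oracle_k2p <- function(a, b) {
  pc <- oracle_pair_counts(a, b)
  P <- pc$ts / pc$n
  Q <- (pc$diffs - pc$ts) / pc$n
  -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
}

oracle_pi <- function(m) {
  n <- nrow(m)
  vals <- c()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      pc <- oracle_pair_counts(m[i, ], m[j, ])
      if (pc$n > 0) vals <- c(vals, pc$diffs / pc$n)
    }
  }
  mean(vals)
}

# exhaustive barcoding-gap scan from a distance matrix and species labels
oracle_gaps <- function(d, sp) {
  multi <- names(which(table(sp) >= 2))
  out <- list()
  for (s in multi) {
    idx <- which(sp == s)
    intra <- -Inf
    for (i in idx) for (j in idx) if (i < j) intra <- max(intra, d[i, j])
    inter <- Inf
    for (i in idx) for (j in which(sp != s)) inter <- min(inter, d[i, j])
    out[[s]] <- list(max_intra = intra, min_inter = inter,
                     has_gap = inter > intra)
  }
  out
}

oracle_zero_stats <- function(d, sp) {
  species <- unique(sp)
  zero_pairs <- 0L
  min_between <- function(a, b) min(d[sp == a, sp == b, drop = FALSE])
  for (i in seq_along(species)) {
    for (j in seq_len(i - 1)) {
      if (min_between(species[i], species[j]) == 0) zero_pairs <- zero_pairs + 1L
    }
  }
  multi <- names(which(table(sp) >= 2))
  zk <- sum(sapply(multi, function(s) {
    min(sapply(setdiff(species, s), function(o) min_between(s, o))) == 0
  }))
  list(zero_k2p = as.integer(zk), zero_k2p_all_pairs = zero_pairs)
}

oracle_amid <- function(d, sp) {
  multi <- names(which(table(sp) >= 2))
  minima <- sapply(multi, function(s) min(d[sp == s, sp != s, drop = FALSE]))
  list(mean = mean(minima), min = min(minima), max = max(minima))
}

# distances implied by a tree (additive matrix)
tree_distances <- function(tree) {
  d <- ape::cophenetic.phylo(tree)
  d[tree$tip.label, tree$tip.label]
}

same_topology <- function(a, b) {
  ape::dist.topo(ape::unroot(a), ape::unroot(b)) == 0
}
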
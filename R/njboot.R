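#' Neighbor-joining tree from a distance matrix
#'
#' Classical Saitou-Nei agglomeration with the standard Q criterion.
#' Negative branch lengths arising at a join are clamped to zero with the
#' remainder shifted to the sibling edge, so path lengths are preserved.
#' Ties in Q are broken by the first (column-major) minimum, which makes the
#' result deterministic.
#'
#' @param dm A `sample_dist` from [distance_matrix()], a symmetric numeric
#'   matrix with dimnames, or a [stats::dist] object.
#' @return An unrooted `phylo` tree (no support values).
#' @export
neighbor_joining <- function(dm) {
  d <- if (inherits(dm, "sample_dist")) dm$values
       else if (inherits(dm, "dist")) as.matrix(dm)
       else dm
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  n <- nrow(d)
  if (n < 3L) stop("neighbor joining needs at least 3 samples")
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  if (any(!is.finite(d))) {
    bad <- which(!is.finite(d), arr.ind = TRUE)[1L, ]
    stop("non-finite distance between ", labels[bad[1L]], " and ",
         labels[bad[2L]])
  }
  # node ids: 1..n tips, internals n+1.. as created
  total <- 2L * n - 2L
  kids <- vector("list", total)
  elen <- vector("list", total)
  active <- seq_len(n)          # node ids of current rows of d
  nextnode <- n
  while (length(active) > 3L) {
    m <- length(active)
    R <- rowSums(d)
    Q <- (m - 2) * d - outer(R, R, "+")
    diag(Q) <- Inf
    k <- which.min(Q)
    i <- (k - 1L) %% m + 1L
    j <- (k - 1L) %/% m + 1L
    li <- 0.5 * d[i, j] + (R[i] - R[j]) / (2 * (m - 2))
    lj <- d[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- max(0, li + lj); lj <- 0 }
    nextnode <- nextnode + 1L
    kids[[nextnode]] <- c(active[i], active[j])
    elen[[nextnode]] <- c(li, lj)
    du <- 0.5 * (d[i, ] + d[j, ] - d[i, j])
    keep <- setdiff(seq_len(m), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], du[keep]),
               c(du[keep], 0))
    active <- c(active[keep], nextnode)
  }
  # final three-point resolution
  a <- d[1L, 2L]; b <- d[1L, 3L]; cc <- d[2L, 3L]
  l1 <- (a + b - cc) / 2
  l2 <- (a + cc - b) / 2
  l3 <- (b + cc - a) / 2
  nextnode <- nextnode + 1L
  kids[[nextnode]] <- active
  elen[[nextnode]] <- pmax(c(l1, l2, l3), 0)
  build_phylo(kids, elen, nextnode, n, labels)
}

# assemble a phylo from children lists, renumbering internals in preorder
build_phylo <- function(kids, elen, root, ntip, labels) {
  n_int <- root - ntip
  newid <- integer(root)
  newid[seq_len(ntip)] <- seq_len(ntip)
  edge <- matrix(0L, ntip + n_int - 1L, 2L)
  edge_len <- numeric(nrow(edge))
  counter <- ntip
  erow <- 0L
  stack <- root
  while (length(stack) > 0L) {
    node <- stack[1L]
    stack <- stack[-1L]
    counter <- counter + 1L
    newid[node] <- counter
    ch <- kids[[node]]
    for (q in seq_along(ch)) {
      erow <- erow + 1L
      edge[erow, ] <- c(newid[node], ch[q])
      edge_len[erow] <- elen[[node]][q]
    }
    stack <- c(ch[ch > ntip], stack)
  }
  int_rows <- edge[, 2L] > ntip
  edge[int_rows, 2L] <- newid[edge[int_rows, 2L]]
  tr <- list(edge = edge, edge.length = edge_len, Nnode = n_int,
             tip.label = labels)
  class(tr) <- "phylo"
  ape::reorder.phylo(tr, "cladewise")
}

#' Bootstrap configuration for [bootstrap_tree()]
#'
#' @param replicates Number of bootstrap replicates (default 1000).
#' @param seed Integer seed controlling the column resampling.
#' @param model Distance model, `"K2P"` or `"raw_differences"`.
#' @export
bootstrap_config <- function(replicates = 1000L, seed = 1L, model = "K2P") {
  stopifnot(replicates >= 1L)
  model <- match.arg(model, c("K2P", "raw_differences"))
  list(replicates = as.integer(replicates), seed = as.integer(seed),
       model = model)
}

#' Neighbor-joining tree with nonparametric bootstrap supports
#'
#' Builds the NJ tree from the full alignment, then resamples alignment
#' columns with replacement `replicates` times, rebuilds the NJ tree for
#' each replicate, and assigns to every internal edge of the original tree
#' the percentage of replicates containing that bipartition.  A replicate in
#' which the K2P distance saturates for some pair falls back to raw
#' differences for that replicate; the number of such fallbacks is recorded.
#' Fully deterministic given the seed.
#'
#' @param aln A [labeled_alignment()].
#' @param cfg A [bootstrap_config()].
#' @return A `phylo` with integer supports as node labels and an `njboot`
#'   attribute (list with `seed`, `replicates`, `model`,
#'   `fallback_replicates`).
#' @export
bootstrap_tree <- function(aln, cfg = bootstrap_config()) {
  m <- aln$matrix
  L <- ncol(m)
  ind <- pair_indicators(m)
  labels <- rownames(m)
  full <- replicate_distance(pair_counts_from_indicators(ind), cfg$model)
  if (full$fallback) {
    warning("K2P saturated on the full alignment; using raw differences")
  }
  dimnames(full$d) <- list(labels, labels)
  tree <- neighbor_joining(full$d)
  target <- tree_split_keys(tree)
  hits <- stats::setNames(integer(length(target)), target)
  fallbacks <- 0L
  with_seed(cfg$seed, {
    for (b in seq_len(cfg$replicates)) {
      cols <- sample.int(L, L, replace = TRUE)
      sub <- lapply(ind, function(x) x[, cols, drop = FALSE])
      rep_d <- replicate_distance(pair_counts_from_indicators(sub), cfg$model)
      if (rep_d$fallback) fallbacks <- fallbacks + 1L
      dimnames(rep_d$d) <- list(labels, labels)
      rep_tree <- neighbor_joining(rep_d$d)
      seen <- tree_split_keys(rep_tree)
      found <- target[target %in% seen]
      hits[found] <- hits[found] + 1L
    }
  })
  support <- 100 * hits / cfg$replicates
  tree <- assign_split_supports(tree, support)
  attr(tree, "njboot") <- list(seed = cfg$seed, replicates = cfg$replicates,
                               model = cfg$model,
                               fallback_replicates = fallbacks)
  tree
}

# distance matrix for one (re)sampled set of columns; K2P falls back to raw
# differences when any pair saturates
replicate_distance <- function(pc, model) {
  if (any(pc$comparable[upper.tri(pc$comparable)] == 0)) {
    stop("a sample pair has no comparable columns")
  }
  if (model == "K2P") {
    P <- pc$transitions / pc$comparable
    Q <- pc$transversions / pc$comparable
    w1 <- 1 - 2 * P - Q
    w2 <- 1 - 2 * Q
    if (all(w1[upper.tri(w1)] > 0 & w2[upper.tri(w2)] > 0)) {
      d <- -0.5 * log(w1) - 0.25 * log(w2)
      diag(d) <- 0
      return(list(d = d, fallback = FALSE))
    }
    return(list(d = pc$diffs, fallback = TRUE))
  }
  list(d = pc$diffs, fallback = FALSE)
}

# write supports (named by canonical split key) onto the node labels of a tree
assign_split_supports <- function(tree, support) {
  ntip <- length(tree$tip.label)
  clades <- clade_tip_sets(tree)
  sup <- rep(NA_real_, tree$Nnode)
  for (i in seq_along(clades)) {
    tips <- clades[[i]]
    if (length(tips) <= 1L || length(tips) >= ntip - 1L) next
    key <- canonical_side(tips, tree$tip.label)
    if (key %in% names(support)) {
      sup[as.integer(names(clades)[i]) - ntip] <- support[[key]]
    }
  }
  set_node_supports(tree, sup)
}

# evaluate an expression with a temporary RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}
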
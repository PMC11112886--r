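#' Collapse poorly supported branches to polytomies
#'
#' Every internal edge whose support value is below `threshold` is
#' contracted (its child node's children are reattached to the parent),
#' mirroring the convention of setting clades with bootstrap support < 50%
#' to polytomy before assessing monophyly.  Edges without a support value
#' are treated as below threshold, with a warning.  Contracted edge lengths
#' are dropped (children keep their own lengths, as in [ape::di2multi()]).
#'
#' @param tree A `phylo` with supports as node labels (see
#'   [read_support_tree()]).
#' @param threshold Support threshold on the 0-100 scale (default 50).
#' @return The collapsed `phylo`; supports of surviving nodes are retained.
#' @export
collapse_low_support <- function(tree, threshold = 50) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  sup <- node_supports(tree)
  root <- ntip + 1L
  parent <- integer(ntip + nnode)
  elen <- rep(NA_real_, ntip + nnode)
  has_len <- !is.null(tree$edge.length)
  for (k in seq_len(nrow(tree$edge))) {
    parent[tree$edge[k, 2L]] <- tree$edge[k, 1L]
    if (has_len) elen[tree$edge[k, 2L]] <- tree$edge.length[k]
  }
  internal <- (ntip + 1L):(ntip + nnode)
  nonroot_int <- setdiff(internal, root)
  missing_sup <- is.na(sup[nonroot_int - ntip])
  if (any(missing_sup)) {
    warning(sum(missing_sup),
            " internal edge(s) without support treated as below threshold")
  }
  collapse <- nonroot_int[is.na(sup[nonroot_int - ntip]) |
                          sup[nonroot_int - ntip] < threshold]
  if (length(collapse) == 0L) return(tree)
  in_collapse <- rep(FALSE, ntip + nnode)
  in_collapse[collapse] <- TRUE
  resolve <- function(p) { while (in_collapse[p]) p <- parent[p]; p }
  keep <- c(seq_len(ntip), setdiff(nonroot_int, collapse))
  new_parent <- integer(ntip + nnode)
  new_len <- rep(NA_real_, ntip + nnode)
  for (x in keep) {
    p <- parent[x]
    while (in_collapse[p]) p <- parent[p]
    new_parent[x] <- p
    new_len[x] <- elen[x]
  }
  # children lists of the contracted tree
  kept_nodes <- c(root, setdiff(nonroot_int, collapse))
  kids <- vector("list", ntip + nnode)
  for (x in keep) kids[[new_parent[x]]] <- c(kids[[new_parent[x]]], x)
  # preorder renumbering of internal nodes
  n_int_new <- length(kept_nodes)
  newid <- integer(ntip + nnode)
  newid[seq_len(ntip)] <- seq_len(ntip)
  counter <- ntip
  edge <- matrix(0L, ntip + n_int_new - 1L, 2L)
  edge_len <- numeric(nrow(edge))
  labels <- character(n_int_new)
  erow <- 0L
  stack <- root
  while (length(stack) > 0L) {
    node <- stack[[1L]]
    stack <- stack[-1L]
    counter <- counter + 1L
    newid[node] <- counter
    labels[counter - ntip] <- if (node == root) {
      if (is.null(tree$node.label)) "" else tree$node.label[1L]
    } else tree$node.label[node - ntip]
    ch <- kids[[node]]
    for (c_ in ch) {
      erow <- erow + 1L
      edge[erow, ] <- c(newid[node], c_)  # child id fixed later if internal
      edge_len[erow] <- new_len[c_]
    }
    stack <- c(ch[ch > ntip], stack)
  }
  # second pass: children that are internal were recorded with old ids
  int_rows <- edge[, 2L] > ntip
  edge[int_rows, 2L] <- newid[edge[int_rows, 2L]]
  out <- list(edge = edge, Nnode = n_int_new, tip.label = tree$tip.label,
              node.label = labels)
  if (has_len) out$edge.length <- edge_len
  class(out) <- "phylo"
  attr(out, "order") <- NULL
  ape::reorder.phylo(out, "cladewise")
}

#' Tree-based monophyly test per multi-individual species
#'
#' After collapsing branches below the support threshold, a species is
#' scored as successfully discriminated when some edge of the (unrooted)
#' tree separates exactly its individuals from all other leaves.  When an
#' outgroup is supplied its leaves are removed first, so the criterion is
#' evaluated against the ingroup only.  The reported support is that of the
#' edge adjacent to the species clade.
#'
#' @param tree A support-labeled `phylo` covering all study samples.
#' @param samples Sample table (`sample_id`, `species`, ...).
#' @param outgroup Optional character vector of outgroup leaf labels.
#' @param threshold Support-collapse threshold (default 50); `NULL` skips
#'   collapsing.
#' @return Data frame of verdicts: `species`, `monophyletic`, `support`,
#'   `n_individuals`, for every species with >= 2 individuals.
#' @export
monophyly_test <- function(tree, samples, outgroup = NULL, threshold = 50) {
  samples <- validate_sample_map(samples)
  missing <- setdiff(samples$sample_id, tree$tip.label)
  if (length(missing) > 0L) {
    stop("samples missing from tree: ", paste(missing, collapse = ", "))
  }
  if (!is.null(outgroup)) {
    og <- intersect(outgroup, tree$tip.label)
    if (length(og) > 0L) tree <- ape::drop.tip(tree, og)
  }
  if (!is.null(threshold)) tree <- collapse_low_support(tree, threshold)
  sizes <- table(samples$species)
  multi <- names(sizes)[sizes >= 2L]
  clades <- clade_tip_sets(tree)
  sup <- node_supports(tree)
  ntip <- length(tree$tip.label)
  keys <- vapply(clades, function(s) paste(sort(s), collapse = "|"),
                 character(1))
  all_tips <- tree$tip.label
  rows <- lapply(multi, function(s) {
    ids <- sort(samples$sample_id[samples$species == s])
    key <- paste(ids, collapse = "|")
    hit <- which(keys == key)
    if (length(hit) == 0L) {
      comp <- paste(sort(setdiff(all_tips, ids)), collapse = "|")
      hit <- which(keys == comp)
    }
    mono <- length(hit) > 0L
    support <- if (mono) sup[as.integer(names(clades)[hit[1L]]) - ntip]
               else NA_real_
    data.frame(species = s, monophyletic = mono, support = support,
               n_individuals = as.integer(sizes[[s]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Species resolution percentage from monophyly verdicts
#'
#' @param verdicts Data frame from [monophyly_test()] (needs a logical
#'   `monophyletic` column).
#' @return Percentage of assessed species scored monophyletic, two-decimal
#'   half-up rounding.
#' @export
resolution <- function(verdicts) {
  if (is.null(verdicts) || nrow(verdicts) == 0L) {
    stop("no verdicts to summarize")
  }
  round_half_up(100 * mean(verdicts$monophyletic), 2L)
}

#' Compare the species identified by two datasets
#'
#' @param verdicts_a,verdicts_b Verdict tables over the same species set.
#' @return List with `gained` (species monophyletic in A but not B), `lost`
#'   (the converse) and `support_shift`, a data frame pairing the supports
#'   of species discriminated by both.
#' @export
compare_datasets <- function(verdicts_a, verdicts_b) {
  if (!setequal(verdicts_a$species, verdicts_b$species)) {
    stop("species universes differ: ",
         paste(c(setdiff(verdicts_a$species, verdicts_b$species),
                 setdiff(verdicts_b$species, verdicts_a$species)),
               collapse = ", "))
  }
  b <- verdicts_b[match(verdicts_a$species, verdicts_b$species), ]
  a <- verdicts_a
  gained <- a$species[a$monophyletic & !b$monophyletic]
  lost <- a$species[!a$monophyletic & b$monophyletic]
  both <- a$monophyletic & b$monophyletic
  shift <- data.frame(species = a$species[both],
                      support_a = a$support[both],
                      support_b = b$support[both],
                      stringsAsFactors = FALSE)
  list(gained = sort(gained), lost = sort(lost), support_shift = shift)
}

#' Support-value summary among discriminated species
#'
#' Bins the supports of successfully discriminated species into
#' `{100, [90,100), [65,90), <65}`, the breakdown used when contrasting
#' plastome-scale and standard barcodes.
#'
#' @param verdicts Verdict table from [monophyly_test()].
#' @return List with counts `n_100`, `n_90_to_100`, `n_65_to_90`,
#'   `n_below_65` and the raw `supports` vector.
#' @export
support_summary <- function(verdicts) {
  sup <- verdicts$support[verdicts$monophyletic]
  sup <- sup[!is.na(sup)]
  list(n_100 = sum(sup == 100),
       n_90_to_100 = sum(sup >= 90 & sup < 100),
       n_65_to_90 = sum(sup >= 65 & sup < 90),
       n_below_65 = sum(sup < 65),
       supports = sup)
}

#' Tree-based evaluation of one barcoding dataset
#'
#' @param tree A support-labeled `phylo`.
#' @param samples Sample table; defaults to `aln$samples` when an alignment
#'   is given instead.
#' @param outgroup,threshold Passed to [monophyly_test()].
#' @param dataset Dataset name for the report.
#' @return A [discrimination_report()] with the verdicts as species table
#'   and `resolution_pct` plus the support histogram in the summary.
#' @export
evaluate_tree <- function(tree, samples, outgroup = NULL, threshold = 50,
                          dataset = "dataset") {
  verdicts <- monophyly_test(tree, samples, outgroup, threshold)
  ss <- support_summary(verdicts)
  species <- data.frame(species = verdicts$species,
                        n_individuals = verdicts$n_individuals,
                        success = verdicts$monophyletic,
                        support = verdicts$support,
                        stringsAsFactors = FALSE)
  discrimination_report(dataset, species, list(
    method = "tree",
    resolution_pct = resolution(verdicts),
    n_assessed = nrow(verdicts), n_success = sum(verdicts$monophyletic),
    support_at_100 = ss$n_100, support_below_65 = ss$n_below_65
  ))
}

#' Select one representative sample per species from a tree
#'
#' Applies, in order: (1) singleton species and monophyletic species retain
#' their samples; (2) own-provenance samples are prioritized over downloaded
#' ones; (3) for non-monophyletic species only individuals placed within
#' their section's dominant clade (the largest clade consisting solely of
#' that section's samples) are kept, excluding strays.  Ties are broken by
#' lexicographic sample id.  Species whose every individual is a stray are
#' flagged and keep their first sample by id.
#'
#' @param tree A `phylo` whose leaves include all samples.
#' @param samples Sample table with `species`, `section` and `provenance`.
#' @return Data frame: `species`, `sample_id`, `monophyletic`, `unresolved`.
#' @export
select_representatives <- function(tree, samples) {
  samples <- validate_sample_map(samples)
  missing <- setdiff(samples$sample_id, tree$tip.label)
  if (length(missing) > 0L) {
    stop("samples missing from tree: ", paste(missing, collapse = ", "))
  }
  clades <- clade_tip_sets(tree)
  keys <- vapply(clades, function(s) paste(sort(s), collapse = "|"),
                 character(1))
  # dominant clade per section: the largest clade whose tips all belong to
  # samples of that section (single tips count as clades of size one)
  section_of <- stats::setNames(samples$section, samples$sample_id)
  dominant <- list()
  for (sec in unique(samples$section)) {
    members <- samples$sample_id[samples$section == sec]
    cand <- c(as.list(members),
              clades[vapply(clades, function(tp) all(tp %in% members),
                            logical(1))])
    sizes <- lengths(cand)
    best <- cand[sizes == max(sizes)]
    first_ids <- vapply(best, function(tp) min(unlist(tp)), character(1))
    dominant[[sec]] <- unlist(best[order(first_ids)][1L])
  }
  sizes <- table(samples$species)
  rows <- lapply(sort(unique(samples$species)), function(s) {
    ids <- sort(samples$sample_id[samples$species == s])
    if (length(ids) == 1L) {
      return(data.frame(species = s, sample_id = ids, monophyletic = TRUE,
                        unresolved = FALSE, stringsAsFactors = FALSE))
    }
    key <- paste(ids, collapse = "|")
    comp <- paste(sort(setdiff(tree$tip.label, ids)), collapse = "|")
    mono <- any(keys == key) || any(keys == comp)
    unresolved <- FALSE
    if (mono) {
      cand <- ids
    } else {
      cand <- ids[vapply(ids, function(id) {
        id %in% dominant[[section_of[[id]]]]
      }, logical(1))]
      if (length(cand) == 0L) {
        unresolved <- TRUE
        cand <- ids
      }
    }
    prov <- samples$provenance[match(cand, samples$sample_id)]
    if (any(prov == "own")) cand <- cand[prov == "own"]
    data.frame(species = s, sample_id = sort(cand)[1L], monophyletic = mono,
               unresolved = unresolved, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Bipartition comparison of two trees (cytonuclear conflict)
#'
#' Compares two phylogenies — typically a plastid and a nuclear tree — at
#' the sample, species or section level.  At the species/section level each
#' group is collapsed to a single leaf only when it is monophyletic in that
#' tree; groups non-monophyletic in either tree are excluded and reported.
#' Both trees are support-collapsed at `threshold` (trees carrying no
#' supports are taken as fully supported), bipartition sets compared over
#' the shared leaf set, and conflicts listed: bipartitions of one collapsed
#' tree incompatible with some bipartition of the other.
#'
#' @param tree_a,tree_b Support-labeled `phylo` objects.
#' @param at `"sample"`, `"species"` or `"section"`.
#' @param samples Sample table (required for species/section level).
#' @param threshold Support threshold (default 50).
#' @return A `tree_comparison`: list with `shared_bipartitions`,
#'   `conflicting_bipartitions` (data frame `tree`, `clade`, `support`,
#'   `max_conflicting_support`), `rf_distance`, `excluded_groups`,
#'   `pruned_leaves`.
#' @export
compare_trees <- function(tree_a, tree_b, at = c("sample", "species", "section"),
                          samples = NULL, threshold = 50) {
  at <- match.arg(at)
  excluded <- character(0)
  if (at != "sample") {
    if (is.null(samples)) stop("species/section comparison needs a sample table")
    ga <- relabel_to_groups(tree_a, samples, at)
    gb <- relabel_to_groups(tree_b, samples, at)
    excluded <- sort(union(ga$excluded, gb$excluded))
    tree_a <- ga$tree
    tree_b <- gb$tree
    # a group non-monophyletic in either tree drops out of both
    drop_a <- intersect(excluded, tree_a$tip.label)
    drop_b <- intersect(excluded, tree_b$tip.label)
    if (length(drop_a) > 0L) tree_a <- ape::drop.tip(tree_a, drop_a)
    if (length(drop_b) > 0L) tree_b <- ape::drop.tip(tree_b, drop_b)
  }
  shared <- intersect(tree_a$tip.label, tree_b$tip.label)
  pruned <- sort(union(setdiff(tree_a$tip.label, shared),
                       setdiff(tree_b$tip.label, shared)))
  if (length(shared) < 4L) stop("fewer than 4 shared leaves")
  tree_a <- ape::keep.tip(tree_a, shared)
  tree_b <- ape::keep.tip(tree_b, shared)
  tree_a <- collapse_if_supported(tree_a, threshold)
  tree_b <- collapse_if_supported(tree_b, threshold)
  sa <- tree_split_keys(tree_a, with_support = TRUE)
  sb <- tree_split_keys(tree_b, with_support = TRUE)
  shared_bip <- intersect(sa$key, sb$key)
  rf <- sum(!(sa$key %in% sb$key)) + sum(!(sb$key %in% sa$key))
  conflicts <- rbind(
    conflict_rows(sa, sb, shared, "A"),
    conflict_rows(sb, sa, shared, "B")
  )
  structure(list(shared_bipartitions = length(shared_bip),
                 conflicting_bipartitions = conflicts,
                 rf_distance = rf,
                 excluded_groups = excluded,
                 pruned_leaves = pruned),
            class = "tree_comparison")
}

#' @export
print.tree_comparison <- function(x, ...) {
  cat("tree_comparison: ", x$shared_bipartitions, " shared bipartitions, ",
      "RF = ", x$rf_distance, ", ", nrow(x$conflicting_bipartitions),
      " conflicting\n", sep = "")
  invisible(x)
}

collapse_if_supported <- function(tree, threshold) {
  sup <- node_supports(tree)
  if (all(is.na(sup))) return(tree)  # unannotated tree: keep fully resolved
  collapse_low_support(tree, threshold)
}

conflict_rows <- function(from, other, leaves, label) {
  if (nrow(from) == 0L) {
    return(data.frame(tree = character(0), clade = character(0),
                      support = numeric(0),
                      max_conflicting_support = numeric(0),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(seq_len(nrow(from)), function(i) {
    x <- strsplit(from$key[i], "|", fixed = TRUE)[[1L]]
    bad <- vapply(other$key, function(k) {
      y <- strsplit(k, "|", fixed = TRUE)[[1L]]
      splits_incompatible(x, y, leaves)
    }, logical(1))
    if (any(bad)) {
      data.frame(tree = label, clade = from$key[i], support = from$support[i],
                 max_conflicting_support = suppressWarnings(
                   max(other$support[bad], na.rm = TRUE)),
                 stringsAsFactors = FALSE)
    } else NULL
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(tree = character(0), clade = character(0),
                      support = numeric(0),
                      max_conflicting_support = numeric(0),
                      stringsAsFactors = FALSE)
  }
  out
}

# two splits of the same leaf set are compatible iff one of the four
# intersections is empty
splits_incompatible <- function(x, y, leaves) {
  n_xy <- length(intersect(x, y))
  n_x_only <- length(setdiff(x, y))
  n_y_only <- length(setdiff(y, x))
  n_neither <- length(leaves) - n_xy - n_x_only - n_y_only
  n_xy > 0L && n_x_only > 0L && n_y_only > 0L && n_neither > 0L
}

# collapse monophyletic species/section groups to single leaves named after
# the group; non-monophyletic groups are excluded (leaves dropped)
relabel_to_groups <- function(tree, samples, at) {
  samples <- validate_sample_map(samples)
  group_of <- if (at == "species") samples$species else samples$section
  names(group_of) <- samples$sample_id
  present <- intersect(tree$tip.label, samples$sample_id)
  clades <- clade_tip_sets(tree)
  keys <- vapply(clades, function(s) paste(sort(s), collapse = "|"),
                 character(1))
  excluded <- character(0)
  for (g in unique(group_of[present])) {
    ids <- sort(names(group_of)[group_of == g & names(group_of) %in% present])
    if (length(ids) == 1L) {
      tree$tip.label[tree$tip.label == ids] <- g
      next
    }
    key <- paste(ids, collapse = "|")
    comp <- paste(sort(setdiff(tree$tip.label, ids)), collapse = "|")
    if (any(keys == key) || any(keys == comp)) {
      tree <- ape::drop.tip(tree, ids[-1L])
      tree$tip.label[tree$tip.label == ids[1L]] <- g
    } else {
      excluded <- c(excluded, g)
      tree <- ape::drop.tip(tree, ids)
    }
    # tip sets shift after dropping; recompute
    clades <- clade_tip_sets(tree)
    keys <- vapply(clades, function(s) paste(sort(s), collapse = "|"),
                   character(1))
  }
  list(tree = tree, excluded = excluded)
}
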
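#' Read a newick tree with branch support values
#'
#' Support values are expected as internal-node labels, either as percentages
#' (`")87:"`) or as proportions (`")0.87:"`).  If every numeric label is at
#' most 1 the whole set is interpreted as proportions and rescaled to the
#' 0-100 scale.  Missing or non-numeric labels become `NA`.
#'
#' @param path Path to a newick file, or a newick string.
#' @return An [ape::read.tree()] `phylo` object whose `node.label` holds
#'   numeric supports in `[0, 100]` (stored as character for newick
#'   round-tripping; use [node_supports()] to obtain the numeric vector).
#' @export
read_support_tree <- function(path) {
  tree <- if (grepl("[(;]", path)) ape::read.tree(text = path)
          else ape::read.tree(path)
  if (is.null(tree)) stop("could not parse newick input")
  normalize_supports(tree)
}

normalize_supports <- function(tree) {
  sup <- node_supports(tree)
  ok <- !is.na(sup)
  if (any(ok) && max(sup[ok]) <= 1) sup[ok] <- sup[ok] * 100
  if (any(ok) && (min(sup[ok]) < 0 || max(sup[ok]) > 100)) {
    stop("support values outside [0, 100]")
  }
  set_node_supports(tree, sup)
}

#' Numeric per-internal-node support values of a tree
#'
#' @param tree A `phylo` object.
#' @return Numeric vector of length `tree$Nnode`; `NA` where no support is
#'   recorded (e.g. the root).
#' @export
node_supports <- function(tree) {
  if (is.null(tree$node.label)) return(rep(NA_real_, tree$Nnode))
  suppressWarnings(as.numeric(tree$node.label))
}

set_node_supports <- function(tree, sup) {
  lab <- ifelse(is.na(sup), "",
                formatC(sup, format = "fg", digits = 6, flag = "-"))
  tree$node.label <- trimws(lab)
  tree
}

#' Write a support-labeled tree to newick
#'
#' @param tree A `phylo` object with supports as node labels.
#' @param path Output path.
#' @export
write_support_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

# canonical representation of one side of a split: the smaller side (ties
# broken toward the side holding the alphabetically first leaf), sorted and
# collapsed with "|".  Complement-invariant, so usable on unrooted trees.
canonical_side <- function(tips, all_tips) {
  other <- setdiff(all_tips, tips)
  side <- if (length(tips) < length(other)) tips
          else if (length(other) < length(tips)) other
          else if (min(tips) < min(other)) tips else other
  paste(sort(side), collapse = "|")
}

# Canonical keys of every nontrivial split (one per internal edge).
tree_split_keys <- function(tree, with_support = FALSE) {
  ntip <- length(tree$tip.label)
  clades <- clade_tip_sets(tree)
  keys <- character(0)
  sup <- numeric(0)
  supports <- node_supports(tree)
  for (i in seq_along(clades)) {
    tips <- clades[[i]]
    if (length(tips) <= 1L || length(tips) >= ntip - 1L) next  # trivial
    keys <- c(keys, canonical_side(tips, tree$tip.label))
    node <- as.integer(names(clades)[i])
    sup <- c(sup, supports[node - ntip])
  }
  dup <- !duplicated(keys)
  if (with_support) {
    data.frame(key = keys[dup], support = sup[dup], stringsAsFactors = FALSE)
  } else {
    unique(keys)
  }
}

# Tip labels descending from each internal node, named by node number.
clade_tip_sets <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  sets <- vector("list", ntip + nnode)
  for (i in seq_len(ntip)) sets[[i]] <- tree$tip.label[i]
  edge <- tree$edge[order(tree$edge[, 1L], decreasing = TRUE), , drop = FALSE]
  # postorder accumulation: children have larger numbers than... not in
  # general, so iterate in reverse cladewise order which visits children first
  tr <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(tr$edge))) {
    p <- tr$edge[k, 1L]
    c_ <- tr$edge[k, 2L]
    sets[[p]] <- c(sets[[p]], sets[[c_]])
  }
  out <- sets[(ntip + 1L):(ntip + nnode)]
  names(out) <- as.character((ntip + 1L):(ntip + nnode))
  out
}
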
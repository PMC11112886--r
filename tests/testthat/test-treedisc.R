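test_that("support collapse contracts exactly the weak edges", {
  # all supports at 100: identity (topology unchanged)
  t100 <- read_support_tree("(((a:1,b:1)100:1,(c:1,d:1)100:1)100:1,e:1,f:1);")
  expect_equal(collapse_low_support(t100)$Nnode, t100$Nnode)
  expect_equal(ape::dist.topo(collapse_low_support(t100), t100), 0,
               ignore_attr = TRUE)
  # fully unsupported tree collapses to a star
  weak <- read_support_tree("(((a:1,b:1)10:1,(c:1,d:1)20:1)30:1,e:1,f:1);")
  star <- collapse_low_support(weak)
  expect_equal(star$Nnode, 1L)
  # supports {90, 40}: exactly one edge contracted
  mix <- read_support_tree("(((a:1,b:1)90:1,(c:1,d:1)40:1)100:1,e:1,f:1);")
  col <- collapse_low_support(mix)
  expect_equal(col$Nnode, mix$Nnode - 1L)
  keys <- superbarcode:::tree_split_keys(col)
  expect_true(paste(sort(c("a", "b")), collapse = "|") %in% keys)
  expect_false(any(grepl("^c\\|d$", keys)))
  # surviving edges keep their lengths; the contracted length is dropped
  d_after <- ape::cophenetic.phylo(col)
  expect_equal(d_after["a", "b"], 2)
  expect_equal(d_after["c", "d"], 2)
  expect_equal(d_after["c", "e"], 3)   # was 4 before contraction
  # missing supports are treated as below threshold, with a warning
  nosup <- ape::read.tree(text = "(((a,b),(c,d)),e,f);")
  expect_warning(st <- collapse_low_support(nosup), "without support")
  expect_equal(st$Nnode, 1L)
})

test_that("monophyly verdicts follow the support-filtered bipartition rule", {
  map <- toy_map(c("a1", "a2", "b1", "b2"))
  good <- read_support_tree("((a1:1,a2:1)90:1,(b1:1,b2:1)80:1);")
  v <- monophyly_test(good, map)
  expect_equal(v$monophyletic, c(TRUE, TRUE))
  expect_equal(v$support, c(90, 80))
  # interleaved individuals: both species fail
  bad <- read_support_tree("((a1:1,b1:1)95:1,(a2:1,b2:1)95:1);")
  vb <- monophyly_test(bad, map)
  expect_equal(vb$monophyletic, c(FALSE, FALSE))
  # support below the threshold destroys the clade
  low <- read_support_tree(
    "(((a1:1,a2:1)40:1,(b1:1,b2:1)90:1)100:1,c1:1,d1:1);")
  map2 <- rbind(map, toy_map(c("c1", "d1")))
  vl <- monophyly_test(low, map2)
  expect_false(vl$monophyletic[vl$species == "A"])
  expect_true(vl$monophyletic[vl$species == "B"])
  # missing samples are named
  expect_error(monophyly_test(good, rbind(map, toy_map("z9"))),
               "missing from tree: z9")
})

test_that("outgroup leaves are excluded before testing the ingroup", {
  # outgroup nested oddly would otherwise break B's bipartition
  tr <- read_support_tree(
    "(((a1:1,a2:1)99:1,og:1)80:1,(b1:1,b2:1)95:1,c1:1);")
  map <- toy_map(c("a1", "a2", "b1", "b2", "c1"))
  v <- monophyly_test(tr, map, outgroup = "og")
  expect_equal(v$monophyletic, c(TRUE, TRUE))
})

test_that("collapse-then-test commutes with support filtering", {
  set.seed(31)
  for (rep in 1:10) {
    tr <- ape::rtree(12)
    tr$tip.label <- sprintf("sp%02d_%d", rep(1:6, each = 2), rep(1:2, 6))
    tr$node.label <- c("", sample(c(10, 40, 60, 80, 100), tr$Nnode - 1, TRUE))
    tr <- superbarcode:::normalize_supports(tr)
    map <- toy_map(tr$tip.label,
                   species = sub("_[12]$", "", tr$tip.label))
    v1 <- monophyly_test(tr, map, threshold = 50)
    collapsed <- suppressWarnings(collapse_low_support(tr, 50))
    v2 <- monophyly_test(collapsed, map, threshold = 50)
    expect_equal(v1$monophyletic, v2$monophyletic)
    expect_equal(v1$support, v2$support)
  }
})

test_that("resolution percentages use half-up rounding", {
  mk <- function(n_yes, n) {
    data.frame(species = sprintf("s%d", 1:n),
               monophyletic = rep(c(TRUE, FALSE), c(n_yes, n - n_yes)),
               support = NA_real_, n_individuals = 2L)
  }
  expect_equal(resolution(mk(19, 21)), 90.48)
  expect_equal(resolution(mk(13, 21)), 61.90)
  expect_equal(resolution(mk(0, 5)), 0)
  expect_error(resolution(mk(0, 5)[0, ]), "no verdicts")
})

test_that("dataset comparison lists gained/lost species and support shifts", {
  a <- data.frame(species = c("s1", "s2", "s3"),
                  monophyletic = c(TRUE, TRUE, FALSE),
                  support = c(100, 90, NA))
  b <- data.frame(species = c("s3", "s1", "s2"),
                  monophyletic = c(TRUE, TRUE, FALSE),
                  support = c(70, 80, NA))
  cmp <- compare_datasets(a, b)
  expect_equal(cmp$gained, "s2")
  expect_equal(cmp$lost, "s3")
  expect_equal(cmp$support_shift$species, "s1")
  expect_equal(cmp$support_shift$support_a, 100)
  expect_equal(cmp$support_shift$support_b, 80)
  same <- compare_datasets(a, a)
  expect_equal(same$gained, character(0))
  expect_equal(same$lost, character(0))
  expect_error(compare_datasets(a, b[1:2, ]), "universes differ")
})

test_that("support summaries bin successes as documented", {
  v <- data.frame(species = sprintf("s%d", 1:6),
                  monophyletic = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
                  support = c(100, 100, 95, 70, 60, NA))
  ss <- support_summary(v)
  expect_equal(ss$n_100, 2)
  expect_equal(ss$n_90_to_100, 1)
  expect_equal(ss$n_65_to_90, 1)
  expect_equal(ss$n_below_65, 1)
  empty <- support_summary(v[v$support > 200 & !is.na(v$support), ])
  expect_equal(empty$n_100, 0)
  expect_length(empty$supports, 0)
})

test_that("representative selection applies the three rules in order", {
  # species A monophyletic (3 samples, one own), B singleton, C strays
  tr <- ape::read.tree(text = paste0(
    "(((a1:1,a2:1,a3:1):1,b1:1):1,((c1:1,x1:1):1,(c2:1,y1:1):1):1);"))
  samples <- data.frame(
    sample_id = c("a1", "a2", "a3", "b1", "c1", "c2", "x1", "y1"),
    species = c("A", "A", "A", "B", "C", "C", "X", "Y"),
    section = c("s1", "s1", "s1", "s1", "s2", "s3", "s2", "s3"),
    provenance = c("downloaded", "own", "downloaded", "own",
                   "own", "own", "own", "own"))
  reps <- select_representatives(tr, samples)
  expect_equal(reps$sample_id[reps$species == "A"], "a2")  # rule 2
  expect_equal(reps$sample_id[reps$species == "B"], "b1")  # rule 1
  # C is non-monophyletic; c1 sits in section s2's clade with x1, c2 in s3's
  expect_equal(reps$sample_id[reps$species == "C"], "c1")
  expect_false(any(reps$unresolved))
})

test_that("a planted stray individual is excluded by the section rule", {
  # sect s1 = {a1,a2,d1}; stray a3 sits inside sect s2's clade
  tr <- ape::read.tree(text =
    "(((a1:1,a2:1):1,d1:1):1,((e1:1,e2:1):1,a3:1):1);")
  samples <- data.frame(
    sample_id = c("a1", "a2", "a3", "d1", "e1", "e2"),
    species = c("A", "A", "A", "D", "E", "E"),
    section = c("s1", "s1", "s1", "s1", "s2", "s2"),
    provenance = "own")
  reps <- select_representatives(tr, samples)
  expect_equal(reps$sample_id[reps$species == "A"], "a1")
  expect_false(reps$monophyletic[reps$species == "A"])
})

test_that("tree comparison counts shared and conflicting bipartitions", {
  t1 <- read_support_tree("((a:1,b:1)90:1,(c:1,d:1)90:1);")
  expect_equal(compare_trees(t1, t1)$rf_distance, 0)
  expect_equal(nrow(compare_trees(t1, t1)$conflicting_bipartitions), 0L)
  # swapped cherries on 4 leaves: textbook RF of 2
  t2 <- read_support_tree("((a:1,c:1)95:1,(b:1,d:1)95:1);")
  cmp <- compare_trees(t1, t2)
  expect_equal(cmp$rf_distance, 2)
  expect_equal(cmp$shared_bipartitions, 0)
  expect_equal(nrow(cmp$conflicting_bipartitions), 2L)
  expect_error(compare_trees(t1, read_support_tree("(a:1,b:1,(x:1,y:1)9:1);")),
               "shared leaves")
})

test_that("a planted NNI rearrangement yields exactly one conflict per tree", {
  base <- "(((a:1,b:1)99:1,(c:1,d:1)99:1)99:1,((e:1,f:1)99:1,g:1)99:1,h:1);"
  nni <- "(((a:1,c:1)97:1,(b:1,d:1)97:1)97:1,((e:1,f:1)99:1,g:1)99:1,h:1);"
  cmp <- compare_trees(read_support_tree(base), read_support_tree(nni))
  cb <- cmp$conflicting_bipartitions
  expect_true(all(c("a|b", "a|c") %in% cb$clade))
  expect_true("b|d" %in% cb$clade)
  # the shared backbone is not flagged
  expect_false(any(grepl("e", cb$clade)))
  expect_equal(cmp$rf_distance, 4)
})

test_that("species-level comparison collapses monophyletic groups only", {
  ta <- read_support_tree(
    "((((a1:1,a2:1)99:1,(b1:1,b2:1)99:1)99:1,f1:1)99:1,(c1:1,c2:1)99:1,d1:1);")
  # in tree B species C is torn apart
  tb <- read_support_tree(
    "((((a1:1,a2:1)99:1,c1:1)99:1,f1:1)99:1,((b1:1,b2:1)99:1,c2:1)99:1,d1:1);")
  samples <- toy_map(c("a1", "a2", "b1", "b2", "c1", "c2", "d1", "f1"))
  cmp <- compare_trees(ta, tb, at = "species", samples = samples)
  expect_equal(cmp$excluded_groups, "C")
  expect_false("C" %in% cmp$pruned_leaves)
  expect_setequal(c("A", "B", "D", "F"),
                  setdiff(c("A", "B", "C", "D", "F"), cmp$excluded_groups))
})
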
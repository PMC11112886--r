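test_that("K2P distance matches the closed form and a counting oracle", {
  expect_equal(k2p_distance("ACGT", "ACGT"), 0)
  # one A->G transition among 10 columns: P = 0.1, Q = 0
  expect_equal(k2p_distance("AAAAAAAAAA", "GAAAAAAAAA"), -0.5 * log(0.8))
  # random 100-column pairs vs the per-site counting oracle
  set.seed(21)
  for (i in 1:20) {
    a <- sample(c(BASES, "-", "N"), 100, TRUE, prob = c(rep(0.23, 4), .04, .04))
    b <- ifelse(runif(100) < 0.1, sample(BASES, 100, TRUE), a)
    b[a == "-"] <- sample(BASES, sum(a == "-"), TRUE)
    expect_equal(k2p_distance(a, b), oracle_k2p(a, b), tolerance = 1e-12)
  }
  # saturation is an error, not a clamp
  expect_error(k2p_distance("AAAA", "GGGG"), "saturation")
  expect_error(k2p_distance("----", "AAAA"), "comparable")
})

test_that("distance matrices are symmetric and match the pairwise oracle", {
  aln <- rand_aln(n = 6, L = 150, seed = 3, gap_frac = 0.05, amb_frac = 0.02)
  # rand_aln columns are near-independent draws, so K2P may saturate;
  # use a clustered alignment for the K2P branch
  cl <- clustered_aln(c(2, 2, 2), L = 150, between = 10, within = 2, seed = 3)
  for (model in c("K2P", "raw_differences")) {
    dm <- distance_matrix(cl, model)
    expect_identical(dm$values, t(dm$values))
    expect_true(all(diag(dm$values) == 0))
    m <- cl$matrix
    for (i in 1:5) for (j in (i + 1):6) {
      expected <- if (model == "K2P") oracle_k2p(m[i, ], m[j, ])
                  else oracle_pair_counts(m[i, ], m[j, ])$diffs
      expect_equal(dm$values[i, j], expected, tolerance = 1e-12)
    }
  }
  # identical rows give a zero matrix; raw differences count literally
  same <- labeled_alignment(c(a = "ACGT", b = "ACGT", c = "ACGT"),
                            toy_map(letters[1:3]))
  expect_true(all(distance_matrix(same, "raw_differences")$values == 0))
  pair <- labeled_alignment(c(a = "AAT", b = "AAC", c = "AAT"),
                            toy_map(letters[1:3]))
  expect_equal(distance_matrix(pair, "raw_differences")$values["a", "b"], 1)
})

test_that("K2P agrees with ape::dist.dna on gap-free alignments", {
  cl <- clustered_aln(c(2, 2, 2, 2), L = 400, between = 25, within = 3,
                      seed = 8)
  dm <- distance_matrix(cl, "K2P")
  bin <- ape::as.DNAbin(tolower(cl$matrix))
  ref <- as.matrix(ape::dist.dna(bin, model = "K80"))
  expect_equal(dm$values, ref[rownames(dm$values), colnames(dm$values)],
               tolerance = 1e-10)
})

test_that("K2P dominates the raw p-distance and respects symmetry ops", {
  cl <- clustered_aln(c(3, 3), L = 300, between = 30, within = 4, seed = 5)
  k2p <- distance_matrix(cl, "K2P")$values
  raw <- distance_matrix(cl, "raw_differences")$values / aln_length(cl)
  expect_true(all(k2p >= raw - 1e-12))
  expect_true(all((k2p == 0) == (raw == 0)))
  # complementing both sequences swaps transition partners but keeps d
  comp <- cl
  comp$matrix[] <- c(A = "T", C = "G", G = "C", T = "A")[cl$matrix]
  expect_equal(distance_matrix(comp, "K2P")$values, k2p, tolerance = 1e-12)
})

test_that("barcoding gaps follow the strict-inequality rule", {
  sp <- c("X", "X", "Y", "Y", "Z")
  ids <- sprintf("s%d", 1:5)
  d <- matrix(0.02, 5, 5, dimnames = list(ids, ids))
  diag(d) <- 0
  d[1, 2] <- d[2, 1] <- 0.01          # X intra
  d[3, 4] <- d[4, 3] <- 0.015         # Y intra
  d[2, 3] <- d[3, 2] <- 0.015         # Y's min inter ties its max intra
  dm <- structure(list(values = d, model = "K2P", deletion = "pairwise",
                       samples = toy_map(ids, species = sp)),
                  class = "sample_dist")
  g <- barcoding_gaps(dm)
  expect_equal(g$species, c("X", "Y"))
  expect_true(g$has_gap[g$species == "X"])    # 0.01 < 0.015
  expect_false(g$has_gap[g$species == "Y"])   # tie counts as failure
  expect_equal(g$nearest_other[g$species == "X"], "Y")
  # singleton-only sample set warns and returns empty
  solo <- structure(list(values = d[4:5, 4:5], model = "K2P",
                         deletion = "pairwise",
                         samples = toy_map(ids[4:5], species = c("Y", "Z"))),
                    class = "sample_dist")
  expect_warning(res <- barcoding_gaps(solo), "no species")
  expect_equal(nrow(res), 0L)
})

test_that("gap verdicts, zero-K2P and AMID match exhaustive scans", {
  for (seed in 1:6) {
    cl <- clustered_aln(c(2, 3, 2, 1, 1), L = 250, between = 12, within = 2,
                        seed = seed)
    dm <- distance_matrix(cl, "K2P")
    sp <- cl$samples$species
    g <- barcoding_gaps(dm)
    og <- oracle_gaps(dm$values, sp)
    for (k in seq_len(nrow(g))) {
      s <- g$species[k]
      expect_equal(g$max_intra[k], og[[s]]$max_intra)
      expect_equal(g$min_inter[k], og[[s]]$min_inter)
      expect_equal(g$has_gap[k], og[[s]]$has_gap)
    }
    zk <- zero_k2p_stats(dm)
    ozk <- oracle_zero_stats(dm$values, sp)
    expect_equal(zk, ozk)
    raw <- distance_matrix(cl, "raw_differences")
    expect_equal(amid(raw), oracle_amid(raw$values, sp))
  }
})

test_that("shared haplotypes produce the defined zero-K2P counts", {
  cl <- clustered_aln(c(2, 2, 2, 1), L = 200, between = 15, within = 0,
                      seed = 4)
  # plant: sp04 (singleton) carries exactly sp01's haplotype
  cl$matrix["sp04_1", ] <- cl$matrix["sp01_1", ]
  dm <- distance_matrix(cl, "K2P")
  zk <- zero_k2p_stats(dm)
  expect_equal(zk$zero_k2p_all_pairs, 1L)     # the pair counted once
  expect_equal(zk$zero_k2p, 1L)               # sp01 is multi-individual
  expect_equal(zk, oracle_zero_stats(dm$values, cl$samples$species))
})

test_that("AMID arithmetic and range reporting", {
  ids <- c("a1", "a2", "b1", "b2")
  sp <- c("A", "A", "B", "B")
  d <- matrix(50, 4, 4, dimnames = list(ids, ids))
  diag(d) <- 0
  d[1, 2] <- d[2, 1] <- d[3, 4] <- d[4, 3] <- 2
  dm <- structure(list(values = d, model = "raw_differences",
                       deletion = "pairwise",
                       samples = toy_map(ids, species = sp)),
                  class = "sample_dist")
  am <- amid(dm)
  expect_equal(am$mean, 50)
  expect_equal(c(am$min, am$max), c(50, 50))
  # minima {20, 1004} -> mean 512 (planted via a third, singleton species)
  ids3 <- c(ids, "c1")
  sp3 <- c(sp, "C")
  d3 <- matrix(2000, 5, 5, dimnames = list(ids3, ids3))
  diag(d3) <- 0
  d3[1:2, 3:4] <- d3[3:4, 1:2] <- 2000
  d3[1:2, 5] <- d3[5, 1:2] <- 20
  d3[3:4, 5] <- d3[5, 3:4] <- 1004
  dm <- structure(list(values = d3, model = "raw_differences",
                       deletion = "pairwise",
                       samples = toy_map(ids3, species = sp3)),
                  class = "sample_dist")
  am <- amid(dm)
  expect_equal(am$mean, 512)
  expect_equal(c(am$min, am$max), c(20, 1004))
  expect_error(amid(structure(list(values = d, model = "K2P",
                                   samples = dm$samples),
                              class = "sample_dist")),
               "raw-difference")
})

test_that("resolution regression on 0K2P recovers planted relationships", {
  # perfectly anti-correlated toy points
  toy <- data.frame(resolution_pct = c(90, 80, 70, 60),
                    zero_k2p = c(0, 1, 2, 3))
  fit <- resolution_vs_zero_k2p(toy)
  expect_equal(fit$r, -1)
  expect_equal(fit$slope, -10)
  # constant resolution: slope and r are zero
  flat <- data.frame(resolution_pct = c(80, 80, 80), zero_k2p = c(0, 1, 2))
  ffit <- resolution_vs_zero_k2p(flat)
  expect_equal(ffit$slope, 0)
  expect_equal(ffit$r, 0)
  expect_error(resolution_vs_zero_k2p(
    data.frame(resolution_pct = c(1, 2, 3), zero_k2p = c(1, 1, 1))),
    "zero variance")
  # noisy planted negative trend: sign recovered
  set.seed(2)
  ok <- 0
  for (rep in 1:20) {
    zk <- 0:7
    res <- 95 - 4 * zk + rnorm(8, 0, 3)
    f <- resolution_vs_zero_k2p(data.frame(resolution_pct = res, zero_k2p = zk))
    if (f$slope < 0 && f$r < 0) ok <- ok + 1
  }
  expect_gte(ok, 19)
})

test_that("complete deletion drops gap columns for every pair", {
  aln <- labeled_alignment(c(a = "ACGTAC", b = "ACGTAC", c = "AC-TGC"),
                           toy_map(letters[1:3]))
  dm <- distance_matrix(aln, "raw_differences", deletion = "complete")
  # column 3 dropped for all pairs; a/b identical, c differs at column 5
  expect_equal(dm$values["a", "b"], 0)
  expect_equal(dm$values["a", "c"], 1)
})

test_that("distance matrices export as square TSV and PHYLIP lower triangle", {
  cl <- clustered_aln(c(2, 2), L = 100, between = 8, within = 1, seed = 12)
  dm <- distance_matrix(cl, "raw_differences")
  sq <- withr::local_tempfile()
  write_distance_matrix(dm, sq, "square")
  back <- utils::read.delim(sq, check.names = FALSE)
  expect_equal(back$sample_id, rownames(dm$values))
  expect_equal(as.matrix(back[, -1]), dm$values, ignore_attr = TRUE)
  lower <- withr::local_tempfile()
  write_distance_matrix(dm, lower, "lower")
  lines <- readLines(lower)
  expect_equal(lines[1], "4")
  expect_equal(length(strsplit(lines[3], "\t")[[1]]), 2L)
})
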
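#' Scenario configuration for the synthetic data generator
#'
#' The defaults emulate a genus-scale barcoding study: 55 species sampled
#' with 83 individuals (21 species with 2-4 individuals, 34 singletons)
#' across 13 sections, and three markers of very different lengths — a long
#' plastid marker, a mid-length nuclear ribosomal marker and a short
#' ITS-like marker.  Between-species divergence is controlled by
#' `interspecific_scale` (expected substitutions/site per unit of
#' species-tree path length) and within-species diversity by
#' `intraspecific_scale` (expected pairwise divergence between conspecific
#' individuals); the defaults put interspecific divergence far above
#' intraspecific diversity, the clean regime in which every discrimination
#' method should succeed.  Chloroplast capture and zero-distance haplotype
#' sharing are off by default and planted explicitly via `capture_events`
#' and `ils_pairs`.
#'
#' @param n_species Number of species.
#' @param individuals_per_species Integer vector (length `n_species`) of
#'   individuals per species.
#' @param marker_names,marker_lengths,marker_types Parallel vectors defining
#'   the markers; types are `"plastid"` or `"nuclear"`.
#' @param interspecific_scale Expected substitutions/site between species
#'   per unit path length of the (unit-depth) species tree.
#' @param intraspecific_scale Expected pairwise divergence
#'   (substitutions/site) between conspecific individuals.
#' @param ts_tv_ratio Ratio of the total transition rate to the total
#'   transversion rate (1 = unbiased given the 1:2 class sizes).
#' @param stem_length Extra terminal branch (species-tree units) appended to
#'   every species tip, guaranteeing a minimum interspecific divergence;
#'   models completed speciation.
#' @param gc Equilibrium GC content of the root sequence.
#' @param n_sections Number of sections species are grouped into (by
#'   species-tree clustering).
#' @param capture_events List of `list(donor=, recipient=, markers=)`:
#'   `donor` a species name, `recipient` a sample id, `markers` marker
#'   names or the shorthand `"plastid"`/`"nuclear"`.
#' @param ils_pairs List of `list(species_a=, species_b=, fraction=)`:
#'   on plastid markers, that fraction of `species_b`'s individuals carry an
#'   exact copy of a `species_a` haplotype (ancestral polymorphism).
#' @param seed Integer master seed.
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(n_species = 55L,
                            individuals_per_species = default_sampling(n_species),
                            marker_names = c("plastome", "nrDNA", "ITS"),
                            marker_lengths = c(4000L, 1000L, 300L),
                            marker_types = c("plastid", "nuclear", "nuclear"),
                            interspecific_scale = 0.05,
                            intraspecific_scale = 0.002,
                            ts_tv_ratio = 2,
                            stem_length = 0.1,
                            gc = 0.5,
                            n_sections = 13L,
                            capture_events = list(),
                            ils_pairs = list(),
                            seed = 1L) {
  stopifnot(n_species >= 2L,
            length(individuals_per_species) == n_species,
            all(individuals_per_species >= 1L),
            length(marker_lengths) == length(marker_names),
            length(marker_types) == length(marker_names),
            all(marker_types %in% c("plastid", "nuclear")),
            interspecific_scale > 0, intraspecific_scale >= 0,
            ts_tv_ratio > 0, stem_length >= 0, gc > 0, gc < 1)
  structure(list(
    n_species = as.integer(n_species),
    individuals_per_species = as.integer(individuals_per_species),
    marker_names = marker_names,
    marker_lengths = as.integer(marker_lengths),
    marker_types = marker_types,
    interspecific_scale = interspecific_scale,
    intraspecific_scale = intraspecific_scale,
    ts_tv_ratio = ts_tv_ratio,
    stem_length = stem_length,
    gc = gc,
    n_sections = as.integer(min(n_sections, n_species)),
    capture_events = capture_events,
    ils_pairs = ils_pairs,
    seed = as.integer(seed)
  ), class = "scenario_config")
}

# 21 multi-individual species (16 x 2, 3 x 3, 2 x 4) + 34 singletons = 83
# samples for the default 55 species; smaller counts scale the mix down
default_sampling <- function(n_species) {
  if (n_species >= 55L) {
    c(rep(2L, 16L), rep(3L, 3L), rep(4L, 2L), rep(1L, n_species - 21L))
  } else {
    n_multi <- max(1L, n_species %/% 3L)
    c(rep(2L, n_multi), rep(1L, n_species - n_multi))
  }
}

# independent substream seeds below 2^31, derived from the master seed
seed_for <- function(seed, stream) {
  as.integer((as.double(seed) * 7919 + stream * 104729) %% 2147483647)
}

#' Simulate a species tree (pure-birth, unit depth)
#'
#' @param n_species Number of tips.
#' @param seed Integer seed; the same seed yields the identical tree.
#' @return An ultrametric `phylo` with root depth 1 and tips `sp01`, `sp02`,
#'   ...
#' @export
simulate_species_tree <- function(n_species, seed = 1L) {
  stopifnot(n_species >= 2L)
  tree <- with_seed(seed, ape::rphylo(n_species, birth = 1, death = 0))
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth
  tree$tip.label <- sprintf("sp%02d", seq_len(n_species))
  tree$node.label <- NULL
  tree
}

#' Evolve one marker alignment over a species tree
#'
#' Sequences evolve by a continuous-time two-rate-class (transition /
#' transversion) substitution process — the generating counterpart of the
#' K2P distance estimator.  Species sequences evolve along the species tree
#' (branch lengths x `interspecific_scale`, plus the terminal stem), and
#' each individual is an independent perturbation of its species sequence at
#' half the intraspecific scale, so conspecific individuals differ by
#' `intraspecific_scale` substitutions/site in expectation.
#'
#' @param species_tree A `phylo` from [simulate_species_tree()].
#' @param cfg A [scenario_config()].
#' @param marker_index Index into the configured markers.
#' @return A [labeled_alignment()] for all individuals.
#' @export
evolve_marker <- function(species_tree, cfg, marker_index) {
  stopifnot(marker_index >= 1L, marker_index <= length(cfg$marker_names))
  L <- cfg$marker_lengths[marker_index]
  R <- cfg$ts_tv_ratio
  samples <- scenario_samples(cfg, species_tree)
  with_seed(seed_for(cfg$seed, marker_index), {
    freq <- c((1 - cfg$gc) / 2, cfg$gc / 2, cfg$gc / 2, (1 - cfg$gc) / 2)
    ntip <- length(species_tree$tip.label)
    root <- ntip + 1L
    seqs <- vector("list", ntip + species_tree$Nnode)
    seqs[[root]] <- sample.int(4L, L, replace = TRUE, prob = freq)
    tr <- ape::reorder.phylo(species_tree, "cladewise")
    for (k in seq_len(nrow(tr$edge))) {
      p <- tr$edge[k, 1L]
      ch <- tr$edge[k, 2L]
      d <- tr$edge.length[k]
      if (ch <= ntip) d <- d + cfg$stem_length
      seqs[[ch]] <- mutate_k2p(seqs[[p]], d * cfg$interspecific_scale, R)
    }
    rows <- matrix("", nrow = nrow(samples), ncol = L)
    for (i in seq_len(nrow(samples))) {
      sp_tip <- match(samples$species[i], species_tree$tip.label)
      codes <- mutate_k2p(seqs[[sp_tip]], cfg$intraspecific_scale / 2, R)
      rows[i, ] <- c("A", "C", "G", "T")[codes]
    }
    rownames(rows) <- samples$sample_id
    labeled_alignment(rows, samples, name = cfg$marker_names[marker_index])
  })
}

# one step of the two-class substitution process: codes 1..4 = A,C,G,T
# (transitions 1<->3, 2<->4), branch length d in expected subs/site,
# R = total transition rate / total transversion rate
mutate_k2p <- function(codes, d, R) {
  if (d <= 0) return(codes)
  bt <- d / (2 * (R + 1))          # beta * t, per transversion target
  at <- R * d / (R + 1)            # alpha * t
  p_tv <- 0.25 - 0.25 * exp(-4 * bt)
  p_ts <- 0.25 + 0.25 * exp(-4 * bt) - 0.5 * exp(-2 * (at + bt))
  u <- stats::runif(length(codes))
  ts_partner <- c(3L, 4L, 1L, 2L)[codes]
  tv1 <- c(2L, 1L, 2L, 1L)[codes]
  tv2 <- c(4L, 3L, 4L, 3L)[codes]
  out <- codes
  out[u < p_ts] <- ts_partner[u < p_ts]
  sel <- u >= p_ts & u < p_ts + p_tv
  out[sel] <- tv1[sel]
  sel <- u >= p_ts + p_tv & u < p_ts + 2 * p_tv
  out[sel] <- tv2[sel]
  out
}

# sample table implied by a config: ids sp01_1, sp01_2, ...; sections are
# species-tree clusters so related species share a section
scenario_samples <- function(cfg, species_tree) {
  species <- sprintf("sp%02d", seq_len(cfg$n_species))
  section_of <- section_assignment(species_tree, cfg$n_sections)
  sp <- rep(species, cfg$individuals_per_species)
  idx <- unlist(lapply(cfg$individuals_per_species, seq_len))
  data.frame(sample_id = sprintf("%s_%d", sp, idx),
             species = sp,
             section = unname(section_of[sp]),
             provenance = "own",
             stringsAsFactors = FALSE)
}

section_assignment <- function(species_tree, n_sections) {
  coph <- stats::cophenetic(species_tree)
  cl <- stats::cutree(stats::hclust(stats::as.dist(coph), method = "average"),
                      k = n_sections)
  stats::setNames(sprintf("sect%02d", cl), names(cl))
}

#' Plant chloroplast-capture events into simulated alignments
#'
#' For each configured event, the recipient sample's sequence on the
#' captured markers is replaced by a near-copy (perturbed at the
#' intraspecific scale) of the donor species' first haplotype; other markers
#' are untouched.  The perturbation is seeded per event, so re-applying the
#' same events is idempotent.
#'
#' @param alignments Named list of [labeled_alignment()]s (one per marker).
#' @param cfg A [scenario_config()] with `capture_events`.
#' @return The modified list of alignments.
#' @export
apply_capture <- function(alignments, cfg) {
  for (e in seq_along(cfg$capture_events)) {
    ev <- cfg$capture_events[[e]]
    markers <- resolve_markers(ev$markers, cfg)
    for (mk in markers) {
      aln <- alignments[[mk]]
      if (!ev$recipient %in% rownames(aln$matrix)) {
        stop("unknown recipient sample ", ev$recipient)
      }
      rec_species <- aln$samples$species[match(ev$recipient,
                                               aln$samples$sample_id)]
      if (sum(aln$samples$species == rec_species) < 2L) {
        warning("capture recipient ", ev$recipient,
                " belongs to a singleton species")
      }
      donor_ids <- sort(aln$samples$sample_id[aln$samples$species == ev$donor])
      if (length(donor_ids) == 0L) stop("unknown donor species ", ev$donor)
      donor <- match(aln$matrix[donor_ids[1L], ], c("A", "C", "G", "T"))
      codes <- with_seed(seed_for(cfg$seed, 9000L + 10L * e + match(mk, cfg$marker_names)),
                         mutate_k2p(donor, cfg$intraspecific_scale / 2,
                                    cfg$ts_tv_ratio))
      alignments[[mk]]$matrix[ev$recipient, ] <- c("A", "C", "G", "T")[codes]
    }
  }
  alignments
}

#' Plant zero-distance haplotype sharing (incomplete lineage sorting)
#'
#' For each configured pair, a fraction of `species_b`'s individuals get an
#' exact copy of `species_a`'s first haplotype on every plastid marker,
#' creating species pairs at zero distance (retained ancestral haplotypes).
#'
#' @param alignments Named list of [labeled_alignment()]s.
#' @param cfg A [scenario_config()] with `ils_pairs`.
#' @return The modified list of alignments.
#' @export
apply_ils <- function(alignments, cfg) {
  plastid <- cfg$marker_names[cfg$marker_types == "plastid"]
  for (pr in cfg$ils_pairs) {
    frac <- if (is.null(pr$fraction)) 0.5 else pr$fraction
    for (mk in plastid) {
      aln <- alignments[[mk]]
      a_ids <- sort(aln$samples$sample_id[aln$samples$species == pr$species_a])
      b_ids <- sort(aln$samples$sample_id[aln$samples$species == pr$species_b])
      if (length(a_ids) == 0L || length(b_ids) == 0L) {
        stop("unknown species in ils pair: ", pr$species_a, "/", pr$species_b)
      }
      n_share <- max(1L, ceiling(frac * length(b_ids)))
      share <- b_ids[seq_len(min(n_share, length(b_ids)))]
      for (id in share) {
        alignments[[mk]]$matrix[id, ] <- aln$matrix[a_ids[1L], ]
      }
    }
  }
  alignments
}

resolve_markers <- function(markers, cfg) {
  if (length(markers) == 1L && markers %in% c("plastid", "nuclear")) {
    return(cfg$marker_names[cfg$marker_types == markers])
  }
  unknown <- setdiff(markers, cfg$marker_names)
  if (length(unknown) > 0L) {
    stop("unknown markers: ", paste(unknown, collapse = ", "))
  }
  markers
}

#' Generate a full synthetic scenario in memory
#'
#' Simulates the species tree, evolves every marker, plants the configured
#' capture and haplotype-sharing events, and assembles the ground truth.
#'
#' @param cfg A [scenario_config()].
#' @return List with `alignments` (named list of [labeled_alignment()]s),
#'   `samples`, `species_tree` and `truth` (expected plastid/nuclear
#'   discrimination failures implied by the planted events).
#' @export
make_scenario <- function(cfg) {
  tree <- simulate_species_tree(cfg$n_species, cfg$seed)
  alignments <- lapply(seq_along(cfg$marker_names),
                       function(i) evolve_marker(tree, cfg, i))
  names(alignments) <- cfg$marker_names
  alignments <- apply_capture(alignments, cfg)
  alignments <- apply_ils(alignments, cfg)
  samples <- alignments[[1L]]$samples
  recip_species <- vapply(cfg$capture_events, function(ev) {
    samples$species[match(ev$recipient, samples$sample_id)]
  }, character(1))
  ils_species <- unlist(lapply(cfg$ils_pairs,
                               function(p) c(p$species_a, p$species_b)))
  list(alignments = alignments,
       samples = samples,
       species_tree = tree,
       truth = list(
         expected_plastid_failures = sort(unique(c(recip_species, ils_species))),
         expected_nuclear_failures = character(0),
         capture_recipients = vapply(cfg$capture_events, `[[`, "",
                                     "recipient"),
         ils_pairs = cfg$ils_pairs
       ))
}

#' Write a synthetic scenario to disk
#'
#' Emits one aligned FASTA per marker, the sample map TSV, the species tree
#' as newick and the ground-truth table, all loadable by the package's
#' readers.
#'
#' @param cfg A [scenario_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the [make_scenario()] list, with `$paths` added.
#' @export
emit_scenario <- function(cfg, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sc <- make_scenario(cfg)
  fasta <- file.path(out_dir, paste0(cfg$marker_names, ".fasta"))
  for (i in seq_along(sc$alignments)) {
    write_alignment(sc$alignments[[i]], fasta[i])
  }
  map <- file.path(out_dir, "samples.tsv")
  utils::write.table(sc$samples, map, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  tree_path <- file.path(out_dir, "species_tree.nwk")
  ape::write.tree(sc$species_tree, tree_path)
  truth_path <- file.path(out_dir, "truth.tsv")
  tr <- data.frame(
    key = c(rep("expected_plastid_failure",
                length(sc$truth$expected_plastid_failures)),
            rep("capture_recipient", length(sc$truth$capture_recipients))),
    value = c(sc$truth$expected_plastid_failures,
              sc$truth$capture_recipients),
    stringsAsFactors = FALSE
  )
  utils::write.table(tr, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sc$paths <- list(fasta = stats::setNames(fasta, cfg$marker_names),
                   map = map, tree = tree_path, truth = truth_path)
  invisible(sc)
}
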
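#' Study configuration for [run_study()]
#'
#' @param datasets List of dataset entries, each a list with `code`, either
#'   `alignment` (a [labeled_alignment()]) or `paths` (FASTA path(s),
#'   concatenated in order), and `tree`: a `phylo`, a newick path, or
#'   `"njboot"` to build a bootstrapped NJ tree in-package.
#' @param map Sample map (data frame or TSV path); required when datasets
#'   are given as paths.
#' @param outgroup Optional outgroup leaf labels.
#' @param support_threshold Support-collapse threshold (default 50).
#' @param njboot_replicates Bootstrap replicates for `"njboot"` trees.
#' @param seed Master seed for in-package tree building.
#' @return A list of class `study_config`.
#' @export
study_config <- function(datasets, map = NULL, outgroup = NULL,
                         support_threshold = 50, njboot_replicates = 100L,
                         seed = 1L) {
  codes <- vapply(datasets, `[[`, "", "code")
  if (anyDuplicated(codes)) stop("dataset codes must be unique")
  structure(list(datasets = datasets, map = map, outgroup = outgroup,
                 support_threshold = support_threshold,
                 njboot_replicates = as.integer(njboot_replicates),
                 seed = as.integer(seed)),
            class = "study_config")
}

#' Run the full barcoding evaluation over a set of datasets
#'
#' For every dataset: alignment feature statistics, the distance-based
#' discrimination report (barcoding gaps, 0K2P statistics, AMID) and the
#' tree-based report (monophyly verdicts, resolution, support summary).
#' Across datasets: pairwise gained/lost species comparisons and the
#' regression of resolution on the 0K2P count.  A dataset that fails is
#' skipped and recorded in the log; the remaining datasets still run.
#'
#' @param cfg A [study_config()].
#' @param out_dir Optional directory; when given, `features.tsv`,
#'   `distance_reports.tsv`, `tree_reports.tsv`, `comparison.tsv`,
#'   per-dataset verdict tables and `run_log.txt` are written there.
#' @return List with `features`, `distance_reports`, `tree_reports`
#'   (summary data frames), `verdicts` (per dataset), `comparisons`,
#'   `regression`, `failed` and `log`.
#' @export
run_study <- function(cfg, out_dir = NULL) {
  log_lines <- c(sprintf("superbarcode run_study | seed=%d | support_threshold=%s | njboot_replicates=%d",
                         cfg$seed, format(cfg$support_threshold),
                         cfg$njboot_replicates))
  map <- if (is.character(cfg$map)) read_sample_map(cfg$map) else cfg$map
  features <- list(); dist_rows <- list(); tree_rows <- list()
  verdicts <- list(); failed <- character(0)
  for (ds in cfg$datasets) {
    code <- ds$code
    res <- tryCatch({
      aln <- load_dataset_alignment(ds, map)
      tree <- load_dataset_tree(ds, aln, cfg)
      feat <- features_table(list(aln))
      feat$dataset <- code
      drep <- evaluate_distance(aln)
      trep <- evaluate_tree(tree, aln$samples, cfg$outgroup,
                            cfg$support_threshold, dataset = code)
      list(feat = feat, drep = drep, trep = trep)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed <- c(failed, code)
      log_lines <- c(log_lines,
                     sprintf("dataset %s FAILED: %s", code, conditionMessage(res)))
      next
    }
    log_lines <- c(log_lines, sprintf(
      "dataset %s: distance %.2f%%, tree %.2f%%",
      code, res$drep$summary$resolution_pct, res$trep$summary$resolution_pct))
    features[[code]] <- res$feat
    dist_rows[[code]] <- cbind(data.frame(dataset = code),
                               as.data.frame(res$drep$summary[-1L]))
    tree_rows[[code]] <- cbind(data.frame(dataset = code),
                               as.data.frame(res$trep$summary[-1L]))
    verdicts[[code]] <- res$trep$species
  }
  features <- do.call(rbind, unname(features))
  dist_df <- do.call(rbind, unname(dist_rows))
  tree_df <- do.call(rbind, unname(tree_rows))
  comparisons <- dataset_comparisons(verdicts)
  regression <- NULL
  if (!is.null(dist_df) && nrow(dist_df) >= 3L &&
      stats::var(dist_df$zero_k2p) > 0) {
    regression <- resolution_vs_zero_k2p(dist_df)
    log_lines <- c(log_lines, sprintf(
      "resolution ~ 0K2P: slope=%.4f r=%.4f p=%.4g",
      regression$slope, regression$r, regression$p))
  }
  out <- list(features = features, distance_reports = dist_df,
              tree_reports = tree_df, verdicts = verdicts,
              comparisons = comparisons, regression = regression,
              failed = failed, log = log_lines)
  if (!is.null(out_dir)) write_study_outputs(out, out_dir)
  out
}

load_dataset_alignment <- function(ds, map) {
  if (!is.null(ds$alignment)) {
    aln <- ds$alignment
    if (is.list(aln) && !inherits(aln, "labeled_alignment")) {
      aln <- concatenate(aln, name = ds$code)
    }
    aln$name <- ds$code
    return(aln)
  }
  if (is.null(map)) stop("a sample map is required to load dataset paths")
  parts <- lapply(ds$paths, read_alignment, map_path = map)
  if (length(parts) == 1L) {
    aln <- parts[[1L]]
    aln$name <- ds$code
    aln
  } else {
    concatenate(parts, name = ds$code)
  }
}

load_dataset_tree <- function(ds, aln, cfg) {
  tr <- ds$tree
  if (is.null(tr) || identical(tr, "njboot")) {
    return(bootstrap_tree(aln, bootstrap_config(
      replicates = cfg$njboot_replicates,
      seed = seed_for(cfg$seed, 100L + match(ds$code,
        vapply(cfg$datasets, `[[`, "", "code"))))))
  }
  if (inherits(tr, "phylo")) return(tr)
  read_support_tree(tr)
}

dataset_comparisons <- function(verdicts) {
  codes <- names(verdicts)
  if (length(codes) < 2L) return(NULL)
  rows <- list()
  for (i in seq_along(codes)) {
    for (j in seq_along(codes)) {
      if (i >= j) next
      va <- verdicts[[i]]; vb <- verdicts[[j]]
      va$monophyletic <- va$success; vb$monophyletic <- vb$success
      cmp <- compare_datasets(va, vb)
      if (length(cmp$gained) > 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          dataset_a = codes[i], dataset_b = codes[j], type = "gained",
          species = cmp$gained, stringsAsFactors = FALSE)
      }
      if (length(cmp$lost) > 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          dataset_a = codes[i], dataset_b = codes[j], type = "lost",
          species = cmp$lost, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(dataset_a = character(0), dataset_b = character(0),
                      type = character(0), species = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

write_study_outputs <- function(out, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, file) {
    if (is.null(df)) df <- data.frame()
    utils::write.table(df, file.path(out_dir, file), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wt(out$features, "features.tsv")
  wt(out$distance_reports, "distance_reports.tsv")
  wt(out$tree_reports, "tree_reports.tsv")
  wt(out$comparisons, "comparison.tsv")
  for (code in names(out$verdicts)) {
    wt(out$verdicts[[code]], paste0("verdicts_", code, ".tsv"))
  }
  writeLines(out$log, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}
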
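#' Per-dataset species discrimination report
#'
#' Couples the per-species success/failure table of one barcoding dataset
#' with its dataset-level summary statistics (resolution percentage and, for
#' distance-based evaluation, the zero-K2P counts and AMID).
#'
#' @param dataset Dataset name or code.
#' @param species Data frame with at least columns `species` and `success`
#'   (logical); typically also `n_individuals` and `support` or distance
#'   columns.
#' @param summary Named list of scalar summary statistics.
#' @return An object of class `discrimination_report`.
#' @export
discrimination_report <- function(dataset, species, summary = list()) {
  species <- as.data.frame(species, stringsAsFactors = FALSE)
  if (nrow(species) > 0L && !all(c("species", "success") %in% names(species))) {
    stop("species table needs columns 'species' and 'success'")
  }
  structure(list(dataset = dataset, species = species, summary = summary),
            class = "discrimination_report")
}

#' @export
print.discrimination_report <- function(x, ...) {
  cat("discrimination_report '", x$dataset, "': ", nrow(x$species),
      " species\n", sep = "")
  for (k in names(x$summary)) cat("  ", k, ": ", x$summary[[k]], "\n", sep = "")
  invisible(x)
}

#' Write / read a discrimination report as TSV
#'
#' The file holds a commented preamble (`#dataset`, one `#summary` line per
#' statistic) followed by the per-species table, and round-trips through
#' [read_report()].
#'
#' @param report A [discrimination_report()].
#' @param path Output path.
#' @export
write_report <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#dataset\t", report$dataset), con)
  for (k in names(report$summary)) {
    writeLines(paste0("#summary\t", k, "\t", fmt_scalar(report$summary[[k]])),
               con)
  }
  df <- report$species
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df) > 0L) {
    cells <- vapply(seq_len(nrow(df)), function(i) {
      paste(vapply(df[i, ], fmt_scalar, character(1)), collapse = "\t")
    }, character(1))
    writeLines(cells, con)
  }
  invisible(path)
}

fmt_scalar <- function(x) {
  if (is.numeric(x)) sprintf("%.15g", x) else as.character(x)
}

#' @rdname write_report
#' @param path Path of a file written by [write_report()].
#' @return For [read_report()], the reconstructed [discrimination_report()].
#' @export
read_report <- function(path) {
  lines <- readLines(path)
  is_meta <- startsWith(lines, "#")
  meta <- strsplit(lines[is_meta], "\t", fixed = TRUE)
  dataset <- NULL
  summary <- list()
  for (m in meta) {
    if (m[1L] == "#dataset") dataset <- m[2L]
    if (m[1L] == "#summary") summary[[m[2L]]] <- parse_scalar(m[3L])
  }
  body <- lines[!is_meta]
  header <- strsplit(body[1L], "\t", fixed = TRUE)[[1L]]
  rows <- lapply(body[-1L], function(l) strsplit(l, "\t", fixed = TRUE)[[1L]])
  if (length(rows) == 0L) {
    df <- as.data.frame(stats::setNames(rep(list(character(0)), length(header)),
                                        header), stringsAsFactors = FALSE)
  } else {
    df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
    names(df) <- header
    for (j in seq_along(df)) {
      parsed <- lapply(df[[j]], parse_scalar)
      if (all(vapply(parsed, is.logical, logical(1)))) {
        df[[j]] <- unlist(parsed)
      } else if (all(vapply(parsed, is.numeric, logical(1)) |
                     vapply(parsed, is.na, logical(1)))) {
        df[[j]] <- as.numeric(unlist(parsed))
      }
    }
  }
  discrimination_report(dataset, df, summary)
}

parse_scalar <- function(s) {
  if (s %in% c("TRUE", "FALSE")) return(as.logical(s))
  if (s == "NA") return(NA)
  num <- suppressWarnings(as.numeric(s))
  if (!is.na(num)) return(num)
  s
}
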
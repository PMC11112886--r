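#' Labeled multiple sequence alignments
#'
#' A `labeled_alignment` couples an aligned character matrix (rows = samples,
#' columns = alignment positions) with a sample table mapping every row to a
#' species and, optionally, a section and a provenance flag.  All downstream
#' statistics (site classes, nucleotide diversity, distances, discrimination
#' rates) consume this container.
#'
#' Sequences are uppercase-normalized; `U` is converted to `T` and the gap
#' dialects `.` and `?` to `-`.  IUPAC ambiguity codes are preserved in the
#' matrix; each statistic documents its own treatment of them.  Column
#' coordinates are 1-based inclusive throughout, following base R and the
#' wider R phylogenetics ecosystem.
#'
#' @param matrix Character matrix of single characters, rows named by sample
#'   id, or a character vector of sequence strings named by sample id.
#' @param samples Data frame with columns `sample_id`, `species` and
#'   optionally `section` and `provenance` (`"own"` or `"downloaded"`).
#' @param name Dataset name (e.g. a dataset code or marker name).
#' @param blocks Optional data frame (`name`, `start`, `end`, 1-based
#'   inclusive) recording the column ranges of concatenated members.
#' @return An object of class `labeled_alignment` with elements `name`,
#'   `matrix`, `samples` and `blocks`.
#' @examples
#' aln <- labeled_alignment(
#'   c(s1 = "ACGT", s2 = "ACGA"),
#'   data.frame(sample_id = c("s1", "s2"), species = c("A", "B"))
#' )
#' aln_length(aln)
#' @export
labeled_alignment <- function(matrix, samples, name = "aln", blocks = NULL) {
  if (is.character(matrix) && is.null(dim(matrix))) {
    matrix <- seqs_to_matrix(matrix)
  }
  stopifnot(is.matrix(matrix), is.character(matrix))
  if (ncol(matrix) < 1L) stop("alignment must have at least one column")
  if (is.null(rownames(matrix))) stop("alignment rows must be named by sample id")
  samples <- validate_sample_map(samples)
  missing <- setdiff(rownames(matrix), samples$sample_id)
  if (length(missing) > 0L) {
    stop("unmapped sample ", paste(missing, collapse = ", "))
  }
  samples <- samples[match(rownames(matrix), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  matrix <- normalize_alignment_matrix(matrix)
  if (is.null(blocks)) {
    blocks <- data.frame(name = name, start = 1L, end = ncol(matrix),
                         stringsAsFactors = FALSE)
  }
  structure(
    list(name = name, matrix = matrix, samples = samples, blocks = blocks),
    class = "labeled_alignment"
  )
}

seqs_to_matrix <- function(seqs) {
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    bad <- names(seqs)[lens != lens[1L]][1L]
    stop("ragged alignment: row ", bad, " has length ", nchar(seqs[bad]),
         " but row ", names(seqs)[1L], " has length ", lens[1L])
  }
  m <- do.call(rbind, strsplit(unname(seqs), ""))
  rownames(m) <- names(seqs)
  m
}

normalize_alignment_matrix <- function(m) {
  m[] <- toupper(m)
  m[m == "U"] <- "T"
  m[m == "." | m == "?"] <- "-"
  allowed <- c("A", "C", "G", "T", "-", IUPAC_AMBIGUITY)
  bad <- setdiff(unique(as.vector(m)), allowed)
  if (length(bad) > 0L) {
    stop("invalid characters in alignment: ", paste(bad, collapse = " "))
  }
  m
}

IUPAC_AMBIGUITY <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")

validate_sample_map <- function(samples) {
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  req <- c("sample_id", "species")
  if (!all(req %in% names(samples))) {
    stop("sample map must have columns sample_id and species")
  }
  if (!"section" %in% names(samples)) samples$section <- ""
  if (!"provenance" %in% names(samples)) samples$provenance <- "own"
  samples$section[is.na(samples$section)] <- ""
  dup <- samples$sample_id[duplicated(samples$sample_id)]
  if (length(dup) > 0L) {
    stop("duplicate sample_id in map: ", paste(unique(dup), collapse = ", "))
  }
  if (any(is.na(samples$species) | samples$species == "")) {
    stop("species must be non-empty for every sample")
  }
  if (!all(samples$provenance %in% c("own", "downloaded"))) {
    stop("provenance must be 'own' or 'downloaded'")
  }
  samples[c("sample_id", "species", "section", "provenance")]
}

#' @export
print.labeled_alignment <- function(x, ...) {
  cat("labeled_alignment '", x$name, "': ", nrow(x$matrix), " samples x ",
      ncol(x$matrix), " columns, ", length(unique(x$samples$species)),
      " species, ", nrow(x$blocks), " block(s)\n", sep = "")
  invisible(x)
}

#' Alignment dimensions and grouping helpers
#'
#' @param aln A [labeled_alignment()].
#' @return `aln_length()` the number of columns; `n_samples()` the number of
#'   rows; `species_sizes()` a named integer vector of individuals per
#'   species; `multi_species()` the species sampled with two or more
#'   individuals.
#' @export
aln_length <- function(aln) ncol(aln$matrix)

#' @rdname aln_length
#' @export
n_samples <- function(aln) nrow(aln$matrix)

#' @rdname aln_length
#' @export
species_sizes <- function(aln) {
  tab <- table(aln$samples$species)
  stats::setNames(as.integer(tab), names(tab))
}

#' @rdname aln_length
#' @export
multi_species <- function(aln) {
  sz <- species_sizes(aln)
  names(sz)[sz >= 2L]
}

#' Read a species-labeled alignment from FASTA plus a sample map
#'
#' @param path Path to an aligned (gapped) FASTA file with unique record ids.
#' @param map_path Path to a tab-separated sample map with header columns
#'   `sample_id`, `species` and optionally `section`, `provenance`; or a data
#'   frame with those columns.
#' @param name Dataset name; defaults to the FASTA file name without
#'   extension.
#' @return A [labeled_alignment()].
#' @export
read_alignment <- function(path, map_path, name = NULL) {
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  seqs <- seqinr::read.fasta(path, seqtype = "DNA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  v <- vapply(seqs, function(s) as.character(s)[1L], character(1))
  if (anyDuplicated(names(v))) {
    stop("duplicate FASTA ids: ",
         paste(unique(names(v)[duplicated(names(v))]), collapse = ", "))
  }
  map <- if (is.character(map_path)) read_sample_map(map_path) else map_path
  labeled_alignment(v, map, name = name)
}

#' @rdname read_alignment
#' @export
read_sample_map <- function(map_path) {
  tab <- utils::read.delim(map_path, stringsAsFactors = FALSE,
                           colClasses = "character")
  validate_sample_map(tab)
}

#' Write a labeled alignment back to FASTA (and optionally its map to TSV)
#'
#' @param aln A [labeled_alignment()].
#' @param path Output FASTA path.
#' @param map_path Optional output path for the sample map TSV.
#' @export
write_alignment <- function(aln, path, map_path = NULL) {
  seqs <- apply(aln$matrix, 1L, paste, collapse = "")
  seqinr::write.fasta(as.list(unname(seqs)), names = names(seqs),
                      file.out = path, nbchar = 80)
  if (!is.null(map_path)) {
    utils::write.table(aln$samples, map_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Concatenate alignments over an identical sample set
#'
#' Used to build combined barcoding datasets (e.g. the three standard plastid
#' barcodes, or plastome + nrDNA).  Block boundaries of the members are
#' retained so that per-marker column ranges remain addressable.
#'
#' @param alignments List of [labeled_alignment()] objects sharing the same
#'   sample set (order may differ; the first member's order is used).
#' @param name Name for the combined dataset.
#' @return A [labeled_alignment()] whose length is the sum of member lengths.
#' @export
concatenate <- function(alignments, name = "concat") {
  stopifnot(length(alignments) >= 1L)
  ref <- alignments[[1L]]
  ids <- rownames(ref$matrix)
  for (a in alignments[-1L]) {
    other <- rownames(a$matrix)
    if (!setequal(ids, other)) {
      stop("sample sets differ: ",
           paste(c(setdiff(ids, other), setdiff(other, ids)), collapse = ", "))
    }
  }
  mats <- lapply(alignments, function(a) a$matrix[ids, , drop = FALSE])
  big <- do.call(cbind, mats)
  offset <- 0L
  blocks <- do.call(rbind, lapply(alignments, function(a) {
    b <- a$blocks
    b$start <- b$start + offset
    b$end <- b$end + offset
    offset <<- offset + ncol(a$matrix)
    b
  }))
  rownames(blocks) <- NULL
  labeled_alignment(big, ref$samples, name = name, blocks = blocks)
}

#' Extract a column range as a new labeled alignment
#'
#' @param aln A [labeled_alignment()].
#' @param start,end 1-based inclusive column bounds.
#' @param name Name for the extracted dataset.
#' @return A [labeled_alignment()] over columns `start:end`.
#' @export
subset_columns <- function(aln, start, end, name = NULL) {
  stopifnot(start >= 1L, end <= ncol(aln$matrix), start <= end)
  if (is.null(name)) name <- paste0(aln$name, "_", start, "_", end)
  labeled_alignment(aln$matrix[, start:end, drop = FALSE], aln$samples,
                    name = name)
}
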
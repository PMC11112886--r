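#' Read a long-format monophyly verdict table
#'
#' Reads a TSV with columns `species`, `dataset`, `monophyletic` (`Y`/`N`)
#' and `support`, and splits it into one verdict data frame per dataset,
#' ready for [resolution()], [compare_datasets()] and [support_summary()].
#' The package ships such a table for a worked example: the published
#' monophyly verdicts of 21 multi-individual *Acer* species under four
#' barcoding datasets
#' (`system.file("extdata", "acer_monophyly_verdicts.tsv",
#' package = "superbarcode")`).
#'
#' @param path Path to the TSV.
#' @return Named list of verdict data frames (`species`, `monophyletic`,
#'   `support`, `n_individuals`), one per dataset, in order of appearance.
#' @export
read_verdicts <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("species", "dataset", "monophyletic", "support") %in%
                names(tab)))
  out <- lapply(split(tab, factor(tab$dataset, levels = unique(tab$dataset))),
                function(df) {
    data.frame(species = df$species,
               monophyletic = df$monophyletic == "Y",
               support = as.numeric(df$support),
               n_individuals = NA_integer_,
               stringsAsFactors = FALSE)
  })
  out[unique(tab$dataset)]
}
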
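#' Packaged per-gene tissue-expression tables
#'
#' The package ships the published per-gene expression summaries for the
#' selected tissue-specific genes of both species: for every gene, the mean
#' and SEM of its expression in each of the six tissues. These serve as
#' worked-example fixtures — they can be scored (means-only mode) and tested
#' with the summary-statistics ANOVA without any download.
#'
#' @param species Optional filter, `"human"` or `"mouse"`.
#' @param target_tissue Optional filter by the tissue the genes were
#'   selected for.
#' @return A tibble with columns `species`, `target_tissue`, `gene_symbol`,
#'   `tissue`, `mean`, `sem`, `n` (roster replicate count for that
#'   species/tissue).
#' @export
printed_tables <- function(species = NULL, target_tissue = NULL) {
  path <- system.file("extdata", "tissue_tables.tsv", package = "tissuespec",
                      mustWork = TRUE)
  df <- tibble::as_tibble(read.delim(path, colClasses = c(
    species = "character", target_tissue = "character",
    gene_symbol = "character", tissue = "character",
    mean = "numeric", sem = "numeric")))
  df$n <- printed_replicates(df$species, df$tissue)
  if (!is.null(species)) df <- df[df$species == species, , drop = FALSE]
  if (!is.null(target_tissue)) {
    df <- df[df$target_tissue == target_tissue, , drop = FALSE]
  }
  df
}

#' Roster replicate counts per species and tissue
#'
#' Human tissues were profiled with 2 samples each; mouse tissues with 3,
#' except muscle with 4.
#'
#' @param species,tissue Character vectors, recycled to common length.
#' @return Integer vector of replicate counts.
#' @export
printed_replicates <- function(species, tissue) {
  ifelse(species == "human", 2L, ifelse(tissue == "muscle", 4L, 3L))
}

#' Load a printed table as a scoreable tissue-mean matrix
#'
#' Turns one species/tissue block of [printed_tables()] into a
#' `tissue_mean_matrix` (the published means, replicate counts from the
#' roster), ready for [score_specificity()]. Feature ids are the gene
#' symbols themselves.
#'
#' @param species `"human"` or `"mouse"`.
#' @param target_tissue One of the six tissues.
#' @return A `tissue_mean_matrix` over the table's genes.
#' @export
load_printed_table <- function(species, target_tissue) {
  df <- printed_tables(species, target_tissue)
  if (nrow(df) == 0) {
    stop("no printed table for ", species, " / ", target_tissue, call. = FALSE)
  }
  genes <- unique(df$gene_symbol)
  tissues <- default_tissues()
  means <- matrix(NA_real_, length(genes), length(tissues),
                  dimnames = list(genes, tissues))
  nrep <- means
  idx <- cbind(match(df$gene_symbol, genes), match(df$tissue, tissues))
  means[idx] <- df$mean
  nrep[idx] <- df$n
  new_tissue_mean_matrix(means, nrep, genes, species)
}

#' Group summary for one printed gene row
#'
#' @param species,target_tissue Table selector.
#' @param gene_symbol Gene to extract.
#' @param n Optional replicate-count override (scalar or per tissue); by
#'   default the roster counts.
#' @return A [group_summary()] over the six tissues.
#' @export
printed_gene_summary <- function(species, target_tissue, gene_symbol, n = NULL) {
  df <- printed_tables(species, target_tissue)
  df <- df[df$gene_symbol == gene_symbol, , drop = FALSE]
  if (nrow(df) == 0) {
    stop("gene ", gene_symbol, " not in the ", species, " ", target_tissue,
         " table", call. = FALSE)
  }
  df <- df[match(default_tissues(), df$tissue), , drop = FALSE]
  group_summary(df$tissue, df$mean, df$sem, if (is.null(n)) df$n else n)
}
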
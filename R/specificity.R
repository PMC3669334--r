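#' Average replicate samples into per-tissue means
#'
#' For every feature and tissue, takes the arithmetic mean over the
#' non-missing replicate values of that tissue's samples. A cell with no
#' non-missing replicate is undefined (`NA`), and the replicate count
#' records how many values actually entered each mean.
#'
#' @param dataset An [expression_dataset()] containing (at least) the mapped
#'   samples.
#' @param map A [tissue_sample_map()].
#' @return An object of class `tissue_mean_matrix` with elements
#'   `means` (feature x tissue), `n_replicates` (same shape, integer),
#'   `feature_ids`, `gene_symbols`, `tissue_names`, `species_label`.
#' @export
compute_tissue_means <- function(dataset, map) {
  dataset <- subset_by_tissue_map(dataset, map)
  tn <- map$tissue_names
  means <- matrix(NA_real_, length(dataset$feature_ids), length(tn),
                  dimnames = list(dataset$feature_ids, tn))
  nrep <- matrix(0L, length(dataset$feature_ids), length(tn),
                 dimnames = list(dataset$feature_ids, tn))
  for (t in tn) {
    sub <- dataset$values[, map$assignments[[t]], drop = FALSE]
    n <- rowSums(!is.na(sub))
    m <- rowMeans(sub, na.rm = TRUE)
    m[n == 0] <- NA_real_
    means[, t] <- m
    nrep[, t] <- as.integer(n)
  }
  new_tissue_mean_matrix(means, nrep, dataset$gene_symbols,
                         dataset$species_label)
}

new_tissue_mean_matrix <- function(means, n_replicates, gene_symbols,
                                   species_label = "unknown") {
  stopifnot(is.matrix(means), !is.null(rownames(means)),
            !is.null(colnames(means)),
            length(gene_symbols) == nrow(means))
  structure(
    list(means = means, n_replicates = n_replicates,
         feature_ids = rownames(means), gene_symbols = as.character(gene_symbols),
         tissue_names = colnames(means), species_label = species_label),
    class = "tissue_mean_matrix"
  )
}

#' Build a tissue-mean matrix directly from known means
#'
#' Wraps an already-averaged feature x tissue matrix (e.g. published table
#' means) as a `tissue_mean_matrix` so it can be scored. Replicate counts
#' default to 1 per cell (means-only fixture mode).
#'
#' @param means Numeric matrix with feature row names and tissue column
#'   names.
#' @param gene_symbols Per-row symbols; defaults to the row names.
#' @param n_replicates Replicate counts, recycled to the matrix shape.
#' @param species_label Species tag.
#' @return A `tissue_mean_matrix`.
#' @export
tissue_mean_matrix <- function(means, gene_symbols = rownames(means),
                               n_replicates = 1L,
                               species_label = "unknown") {
  means <- as.matrix(means)
  nrep <- matrix(as.integer(n_replicates), nrow(means), ncol(means),
                 dimnames = dimnames(means))
  new_tissue_mean_matrix(means, nrep, gene_symbols, species_label)
}

#' @export
print.tissue_mean_matrix <- function(x, ...) {
  cat(sprintf("<tissue_mean_matrix> %s: %d features x %d tissues (%s)\n",
              x$species_label, nrow(x$means), ncol(x$means),
              paste(x$tissue_names, collapse = ", ")))
  invisible(x)
}

#' Score tissue specificity for one target tissue
#'
#' Two equivalent ratio scores are computed per feature. With `m_t` the
#' target-tissue mean and `m_1..m_k` the other tissues' means:
#' \describe{
#'   \item{`score_i`}{mean over other tissues of `m_j / m_t`; low values
#'     mean high target specificity (sort ascending).}
#'   \item{`score_v`}{`m_t` divided by the mean of the other tissues' means;
#'     high values mean high target specificity (sort descending).}
#' }
#' Because every ratio in `score_i` shares the denominator `m_t`, the two
#' scores are exact reciprocals and induce the same ranking. Features with
#' an undefined or non-positive target mean, or any undefined non-target
#' mean, are excluded with a reason instead of scored.
#'
#' @param means A `tissue_mean_matrix` (see [compute_tissue_means()]).
#' @param target Target tissue name; must be one of `means$tissue_names`.
#' @return A tibble with one row per feature: `feature_id`, `gene_symbol`,
#'   `target_tissue`, `score_i`, `score_v`, one `ratio_<tissue>` column per
#'   tissue (`m_tissue / m_target`; 1 for the target itself), and
#'   `excluded_reason` (empty string when scored).
#' @export
score_specificity <- function(means, target) {
  stopifnot(inherits(means, "tissue_mean_matrix"))
  if (!(target %in% means$tissue_names)) {
    stop("unknown target tissue '", target, "'; available: ",
         paste(means$tissue_names, collapse = ", "), call. = FALSE)
  }
  if (length(means$tissue_names) < 2) {
    stop("at least two tissues are required to score specificity",
         call. = FALSE)
  }
  m <- means$means
  mt <- m[, target]
  others <- m[, setdiff(means$tissue_names, target), drop = FALSE]

  reason <- rep("", nrow(m))
  reason[apply(others, 1L, anyNA)] <- "undefined non-target mean"
  reason[!is.na(mt) & mt <= 0] <- "nonpositive target mean"
  reason[is.na(mt)] <- "undefined target mean"
  ok <- reason == ""

  score_i <- score_v <- rep(NA_real_, nrow(m))
  other_mean <- rowMeans(others)
  score_i[ok] <- other_mean[ok] / mt[ok]
  score_v[ok] <- mt[ok] / other_mean[ok]

  ratios <- matrix(NA_real_, nrow(m), ncol(m),
                   dimnames = list(rownames(m), means$tissue_names))
  ratios[ok, ] <- m[ok, , drop = FALSE] / mt[ok]
  colnames(ratios) <- paste0("ratio_", means$tissue_names)

  out <- tibble::tibble(
    feature_id = means$feature_ids,
    gene_symbol = means$gene_symbols,
    target_tissue = target,
    score_i = score_i,
    score_v = score_v
  )
  out <- dplyr::bind_cols(out, tibble::as_tibble(ratios))
  out$excluded_reason <- reason
  out
}

#' Rank features or genes by tissue specificity
#'
#' Sorts scored features ascending by `score_i` (equivalently descending by
#' `score_v`), assigns 1-based ranks, and places excluded features after all
#' scored ones. Ties break by gene symbol, then feature id. At
#' `level = "gene"`, each symbol keeps only its best-ranked feature
#' (unannotated probes, symbol `""`, are kept per probe); ranks are then
#' reassigned over the collapsed table.
#'
#' @param results Scored tibble from [score_specificity()], all rows sharing
#'   one target tissue.
#' @param level `"probe"` (default) or `"gene"`.
#' @return The input tibble, sorted, with a leading 1-based `rank` column.
#' @export
rank_by_specificity <- function(results, level = c("probe", "gene")) {
  level <- match.arg(level)
  stopifnot(is.data.frame(results),
            all(c("feature_id", "gene_symbol", "score_i", "target_tissue",
                  "excluded_reason") %in% names(results)))
  if (length(unique(results$target_tissue)) > 1) {
    stop("results mix target tissues: ",
         paste(unique(results$target_tissue), collapse = ", "), call. = FALSE)
  }
  excluded <- results$excluded_reason != ""
  ord <- order(excluded, results$score_i, results$gene_symbol,
               results$feature_id, method = "radix")
  out <- results[ord, , drop = FALSE]
  if (level == "gene") {
    collapsible <- nzchar(out$gene_symbol)
    keep <- !collapsible | !duplicated(out$gene_symbol)
    out <- out[keep, , drop = FALSE]
  }
  out$rank <- seq_len(nrow(out))
  dplyr::relocate(out, "rank")
}

#' Write a ranked specificity table as TSV
#'
#' Numeric columns are written at six significant digits so that repeated
#' runs on identical inputs are byte-identical.
#'
#' @param ranked Tibble from [rank_by_specificity()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ranked_table <- function(ranked, path) {
  write_tsv6(ranked, path)
  invisible(path)
}

# fixed 6-significant-digit formatting for stable, diff-able outputs
write_tsv6 <- function(df, path) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) {
      x <- df[[j]]
      df[[j]] <- ifelse(is.na(x), "NA",
                        trimws(formatC(signif(x, 6), format = "g", digits = 6)))
    }
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
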
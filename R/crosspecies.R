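#' Normalize gene symbols for cross-species matching
#'
#' Case differences are the dominant cosmetic difference between human
#' (SLC34A1) and mouse (Slc34a1) symbol conventions, so the default
#' normalization is uppercasing. An explicit two-column ortholog map
#' overrides it: symbols found in the map (matched case-insensitively) are
#' replaced by their mapped partner's uppercased symbol.
#'
#' @param symbols Character vector of symbols.
#' @param ortholog_map Optional data frame with columns `symbol_a`,
#'   `symbol_b`; `side` selects which column `symbols` belongs to.
#' @param side `"a"` or `"b"`.
#' @return Character vector of normalized symbols (`""` stays `""`).
#' @export
normalize_symbols <- function(symbols, ortholog_map = NULL, side = c("a", "b")) {
  side <- match.arg(side)
  out <- toupper(symbols)
  out[is.na(symbols)] <- ""
  if (!is.null(ortholog_map)) {
    stopifnot(all(c("symbol_a", "symbol_b") %in% names(ortholog_map)))
    from <- toupper(ortholog_map[[paste0("symbol_", side)]])
    # both sides collapse onto the uppercased species-A symbol
    to <- toupper(ortholog_map$symbol_a)
    hit <- match(out, from)
    out[!is.na(hit)] <- to[hit[!is.na(hit)]]
  }
  out
}

#' Read a two-column ortholog map
#'
#' @param path TSV with header columns `symbol_a` and `symbol_b`.
#' @return A tibble with those two columns.
#' @export
read_ortholog_map <- function(path) {
  df <- read.delim(path, colClasses = "character")
  if (!all(c("symbol_a", "symbol_b") %in% names(df))) {
    stop("ortholog map needs columns 'symbol_a' and 'symbol_b': ", path,
         call. = FALSE)
  }
  tibble::as_tibble(df[, c("symbol_a", "symbol_b")])
}

top_k_genes <- function(ranked, k, ortholog_map, side) {
  scored <- ranked[ranked$excluded_reason == "" & ranked$rank <= k, , drop = FALSE]
  scored$.norm <- normalize_symbols(scored$gene_symbol, ortholog_map, side)
  scored[nzchar(scored$.norm), , drop = FALSE]
}

#' Intersect two species' top-ranked gene lists
#'
#' Takes the gene-level ranked tables of two species for the same target
#' tissue and returns the genes whose (normalized) symbol lies within the
#' top `k` of both, sorted by the sum of the two ranks (ties by symbol).
#'
#' @param ranked_a,ranked_b Gene-level ranked tibbles from
#'   [rank_by_specificity()], same target tissue.
#' @param k Positive integer rank cutoff (default 100).
#' @param ortholog_map Optional two-column map (see [read_ortholog_map()]);
#'   by default symbols match case-insensitively.
#' @return A tibble: `gene_symbol` (normalized), `target_tissue`,
#'   `symbol_a`, `rank_a`, `score_v_a`, `symbol_b`, `rank_b`, `score_v_b`,
#'   `flag` (`"both"`).
#' @export
intersect_top_ranked <- function(ranked_a, ranked_b, k = 100,
                                 ortholog_map = NULL) {
  if (!is.numeric(k) || length(k) != 1 || is.na(k) || k < 1) {
    stop("k must be a positive integer", call. = FALSE)
  }
  check_same_target(ranked_a, ranked_b)
  a <- top_k_genes(ranked_a, k, ortholog_map, "a")
  b <- top_k_genes(ranked_b, k, ortholog_map, "b")
  common <- intersect(a$.norm, b$.norm)
  ia <- match(common, a$.norm)
  ib <- match(common, b$.norm)
  out <- tibble::tibble(
    gene_symbol = common,
    target_tissue = if (nrow(ranked_a)) ranked_a$target_tissue[1] else character(0),
    symbol_a = a$gene_symbol[ia], rank_a = a$rank[ia], score_v_a = a$score_v[ia],
    symbol_b = b$gene_symbol[ib], rank_b = b$rank[ib], score_v_b = b$score_v[ib],
    flag = rep("both", length(common))
  )
  out[order(out$rank_a + out$rank_b, out$gene_symbol), , drop = FALSE]
}

check_same_target <- function(ranked_a, ranked_b) {
  ta <- unique(ranked_a$target_tissue)
  tb <- unique(ranked_b$target_tissue)
  if (length(ta) > 1 || length(tb) > 1 ||
      (length(ta) == 1 && length(tb) == 1 && !identical(ta, tb))) {
    stop("ranked tables must share one target tissue (got '",
         paste(ta, collapse = ","), "' vs '", paste(tb, collapse = ","), "')",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Flag top-ranked genes absent from the other platform
#'
#' A gene can only be cross-species confirmed if both platforms measure it.
#' This returns genes within the top `k` of one species whose symbol does
#' not occur anywhere in the other species' annotation (so they could never
#' intersect), flagged `only_in_a_platform` or `only_in_b_platform`. Genes
#' that are present but merely lowly ranked in the other species are not
#' flagged.
#'
#' @inheritParams intersect_top_ranked
#' @return A tibble in the same shape as [intersect_top_ranked()], with the
#'   absent species' columns `NA` and `flag` set accordingly.
#' @export
flag_platform_missing <- function(ranked_a, ranked_b, k = 100,
                                  ortholog_map = NULL) {
  if (!is.numeric(k) || length(k) != 1 || is.na(k) || k < 1) {
    stop("k must be a positive integer", call. = FALSE)
  }
  check_same_target(ranked_a, ranked_b)
  tt <- unique(c(ranked_a$target_tissue, ranked_b$target_tissue))[1]
  all_a <- normalize_symbols(ranked_a$gene_symbol, ortholog_map, "a")
  all_b <- normalize_symbols(ranked_b$gene_symbol, ortholog_map, "b")
  top_a <- top_k_genes(ranked_a, k, ortholog_map, "a")
  top_b <- top_k_genes(ranked_b, k, ortholog_map, "b")

  only_a <- top_a[!(top_a$.norm %in% all_b), , drop = FALSE]
  only_b <- top_b[!(top_b$.norm %in% all_a), , drop = FALSE]
  out <- dplyr::bind_rows(
    tibble::tibble(gene_symbol = only_a$.norm, target_tissue = tt,
                   symbol_a = only_a$gene_symbol, rank_a = only_a$rank,
                   score_v_a = only_a$score_v,
                   symbol_b = NA_character_, rank_b = NA_integer_,
                   score_v_b = NA_real_, flag = "only_in_a_platform"),
    tibble::tibble(gene_symbol = only_b$.norm, target_tissue = tt,
                   symbol_a = NA_character_, rank_a = NA_integer_,
                   score_v_a = NA_real_,
                   symbol_b = only_b$gene_symbol, rank_b = only_b$rank,
                   score_v_b = only_b$score_v, flag = "only_in_b_platform")
  )
  out[order(out$flag, out$gene_symbol), , drop = FALSE]
}
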
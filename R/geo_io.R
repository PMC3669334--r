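MISSING_TOKENS <- c("null", "--", "", "na")

#' Parse a GDS full-SOFT file into an expression dataset
#'
#' Reads the `!dataset_table_begin` ... `!dataset_table_end` block of a GEO
#' DataSet SOFT file (plain or gzip). The table header must start with
#' `ID_REF` and `IDENTIFIER`; every remaining column is taken as one GSM
#' sample. Cells equal to `null`, `--`, `NA` or the empty string (case
#' insensitive) become missing values. Negative intensities, which the
#' ratio statistic cannot use, are clamped to missing with a warning giving
#' their count. All header lines outside the table are retained verbatim in
#' the dataset's `metadata`.
#'
#' @param path Path to a `.soft` or `.soft.gz` file.
#' @param species_label Species tag stored on the dataset; defaults to the
#'   file name.
#' @return An [expression_dataset()].
#' @export
parse_gds_soft <- function(path, species_label = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(species_label)) species_label <- basename(path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con), add = TRUE)
  lines <- readLines(con, warn = FALSE)

  begin <- grep("^!dataset_table_begin", lines)
  end <- grep("^!dataset_table_end", lines)
  if (length(begin) != 1 || length(end) != 1 || end <= begin + 1) {
    stop("not a GDS full-SOFT file: missing !dataset_table_begin/",
         "!dataset_table_end block in ", path, call. = FALSE)
  }
  header <- strsplit(lines[begin + 1], "\t", fixed = TRUE)[[1]]
  if (length(header) < 3 || header[1] != "ID_REF" || header[2] != "IDENTIFIER") {
    stop("malformed dataset table header (line ", begin + 1,
         "): expected ID_REF\tIDENTIFIER\t<GSM...>, got: ",
         lines[begin + 1], call. = FALSE)
  }
  sample_ids <- header[-(1:2)]

  body <- lines[(begin + 2):(end - 1)]
  dt <- data.table::fread(text = body, sep = "\t", header = FALSE,
                          colClasses = "character", na.strings = NULL)
  if (ncol(dt) != length(header)) {
    stop("dataset table rows have ", ncol(dt), " columns but the header has ",
         length(header), call. = FALSE)
  }
  feature_ids <- dt[[1]]
  if (anyDuplicated(feature_ids)) {
    stop("duplicate ID_REF in ", path, ": ",
         paste(head(unique(feature_ids[duplicated(feature_ids)]), 5),
               collapse = ", "), call. = FALSE)
  }
  gene_symbols <- dt[[2]]
  gene_symbols[tolower(gene_symbols) %in% MISSING_TOKENS] <- ""

  values <- matrix(NA_real_, nrow(dt), length(sample_ids))
  for (j in seq_along(sample_ids)) {
    cell <- dt[[j + 2]]
    cell[tolower(cell) %in% MISSING_TOKENS] <- NA
    values[, j] <- suppressWarnings(as.numeric(cell))
  }
  n_neg <- sum(values < 0, na.rm = TRUE)
  if (n_neg > 0) {
    values[!is.na(values) & values < 0] <- NA_real_
    warning(n_neg, " negative value(s) clamped to missing in ", path,
            call. = FALSE)
  }
  metadata <- c(lines[seq_len(begin - 1)],
                if (end < length(lines)) lines[(end + 1):length(lines)])
  metadata <- metadata[startsWith(metadata, "!") | startsWith(metadata, "^") |
                         startsWith(metadata, "#")]
  expression_dataset(values, gene_symbols = gene_symbols,
                     species_label = species_label,
                     feature_ids = feature_ids, sample_ids = sample_ids,
                     metadata = metadata)
}

#' Restrict a dataset to the samples of a tissue map
#'
#' Keeps only the samples named in `map`, with columns reordered so that
#' samples are grouped by tissue, tissues in map order. The result is the
#' canonical input for [compute_tissue_means()].
#'
#' @param dataset An [expression_dataset()].
#' @param map A [tissue_sample_map()]; every referenced sample must exist in
#'   the dataset.
#' @return A new [expression_dataset()] with the mapped samples only.
#' @export
subset_by_tissue_map <- function(dataset, map) {
  stopifnot(inherits(dataset, "expression_dataset"),
            inherits(map, "tissue_sample_map"))
  wanted <- unlist(map$assignments, use.names = FALSE)
  missing <- setdiff(wanted, dataset$sample_ids)
  if (length(missing) > 0) {
    stop("samples named in the tissue map are absent from the dataset: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  expression_dataset(dataset$values[, wanted, drop = FALSE],
                     gene_symbols = dataset$gene_symbols,
                     species_label = dataset$species_label,
                     feature_ids = dataset$feature_ids,
                     sample_ids = wanted,
                     metadata = dataset$metadata)
}
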
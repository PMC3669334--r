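#' Construct an expression dataset
#'
#' An `expression_dataset` holds one species' probe-by-sample intensity
#' matrix together with its probe-to-gene annotation. Intensities are
#' non-negative; missing measurements are `NA`. This is the container the
#' SOFT parser fills and every downstream stage consumes.
#'
#' @param values Numeric matrix, features in rows, samples in columns.
#'   Row names are taken as feature ids and column names as sample ids when
#'   `feature_ids` / `sample_ids` are not given.
#' @param gene_symbols Character vector of per-feature gene symbols; empty
#'   string or `NA` marks an unannotated probe.
#' @param species_label Free-text species tag (e.g. `"human"`).
#' @param feature_ids,sample_ids Optional explicit id vectors.
#' @param metadata Optional character vector of opaque header lines carried
#'   along from a parsed SOFT file.
#'
#' @return An object of class `expression_dataset`.
#' @export
expression_dataset <- function(values, gene_symbols = NULL,
                               species_label = "unknown",
                               feature_ids = NULL, sample_ids = NULL,
                               metadata = character()) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(feature_ids)) feature_ids <- rownames(values)
  if (is.null(sample_ids)) sample_ids <- colnames(values)
  if (is.null(feature_ids) || is.null(sample_ids)) {
    stop("feature_ids and sample_ids must be supplied or present as dimnames",
         call. = FALSE)
  }
  feature_ids <- as.character(feature_ids)
  sample_ids <- as.character(sample_ids)
  if (is.null(gene_symbols)) gene_symbols <- rep("", length(feature_ids))
  gene_symbols <- as.character(gene_symbols)
  gene_symbols[is.na(gene_symbols)] <- ""

  if (nrow(values) != length(feature_ids) || ncol(values) != length(sample_ids)) {
    stop("matrix dimensions do not match the id lists", call. = FALSE)
  }
  if (length(gene_symbols) != length(feature_ids)) {
    stop("gene_symbols must have one entry per feature", call. = FALSE)
  }
  if (anyDuplicated(feature_ids)) {
    stop("duplicate feature ids: ",
         paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(is.infinite(values))) {
    stop("expression values must be finite or NA", call. = FALSE)
  }
  if (any(values < 0, na.rm = TRUE)) {
    stop("expression values must be non-negative; clamp or clean upstream",
         call. = FALSE)
  }
  dimnames(values) <- list(feature_ids, sample_ids)
  structure(
    list(values = values, feature_ids = feature_ids,
         gene_symbols = gene_symbols, sample_ids = sample_ids,
         species_label = species_label, metadata = metadata),
    class = "expression_dataset"
  )
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("<expression_dataset> %s: %d features x %d samples\n",
              x$species_label, length(x$feature_ids), length(x$sample_ids)))
  n_sym <- sum(nzchar(x$gene_symbols))
  cat(sprintf("  annotated features: %d; missing cells: %d\n",
              n_sym, sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$values)

#' Construct a tissue-to-sample assignment
#'
#' Maps each tissue in a panel to the GSM-style sample ids measuring it.
#' Every tissue must have at least one sample and no sample may serve two
#' tissues.
#'
#' @param assignments Named list: tissue name -> character vector of sample
#'   ids.
#' @param tissue_names Optional explicit tissue order; defaults to the order
#'   of `assignments`.
#'
#' @return An object of class `tissue_sample_map`.
#' @export
tissue_sample_map <- function(assignments, tissue_names = names(assignments)) {
  if (is.null(names(assignments)) || any(!nzchar(names(assignments)))) {
    stop("assignments must be a named list of tissue -> sample ids", call. = FALSE)
  }
  if (length(tissue_names) == 0) stop("empty tissue list", call. = FALSE)
  if (!setequal(tissue_names, names(assignments)) ||
      length(tissue_names) != length(assignments)) {
    stop("tissue_names must match the names of assignments", call. = FALSE)
  }
  assignments <- assignments[tissue_names]
  assignments <- lapply(assignments, as.character)
  if (any(lengths(assignments) < 1)) {
    stop("every tissue needs at least one sample; empty: ",
         paste(tissue_names[lengths(assignments) < 1], collapse = ", "),
         call. = FALSE)
  }
  all_samples <- unlist(assignments, use.names = FALSE)
  if (anyDuplicated(all_samples)) {
    stop("sample assigned to more than one tissue: ",
         paste(unique(all_samples[duplicated(all_samples)]), collapse = ", "),
         call. = FALSE)
  }
  structure(list(tissue_names = tissue_names, assignments = assignments),
            class = "tissue_sample_map")
}

#' @export
print.tissue_sample_map <- function(x, ...) {
  cat(sprintf("<tissue_sample_map> %d tissues, %d samples\n",
              length(x$tissue_names), sum(lengths(x$assignments))))
  for (t in x$tissue_names) {
    cat(sprintf("  %s: %s\n", t, paste(x$assignments[[t]], collapse = ", ")))
  }
  invisible(x)
}

#' Read a tissue-sample map from YAML or TSV
#'
#' Two on-disk forms are accepted: a YAML mapping of tissue name to a list
#' of sample ids, or a two-column TSV with header `tissue` and `sample_id`.
#' The format is chosen by extension (`.yml`/`.yaml` vs anything else).
#'
#' @param path Path to the map file.
#' @return A [tissue_sample_map()].
#' @export
read_tissue_map <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    raw <- yaml::read_yaml(path)
    assignments <- lapply(raw, function(x) as.character(unlist(x)))
    return(tissue_sample_map(assignments))
  }
  df <- read.delim(path, colClasses = "character")
  if (!all(c("tissue", "sample_id") %in% names(df))) {
    stop("TSV tissue map needs columns 'tissue' and 'sample_id': ", path,
         call. = FALSE)
  }
  tissues <- unique(df$tissue)
  assignments <- lapply(tissues, function(t) df$sample_id[df$tissue == t])
  names(assignments) <- tissues
  tissue_sample_map(assignments)
}

#' Packaged tissue-sample rosters
#'
#' Returns the packaged six-tissue GSM roster for `"human"` (two samples per
#' tissue, GDS596 sample ids) or `"mouse"` (three per tissue, four for
#' muscle, GDS3142 sample ids).
#'
#' @param species `"human"` or `"mouse"`.
#' @return A [tissue_sample_map()].
#' @export
packaged_tissue_map <- function(species = c("human", "mouse")) {
  species <- match.arg(species)
  path <- system.file("extdata", sprintf("tissue_map_%s.tsv", species),
                      package = "tissuespec", mustWork = TRUE)
  read_tissue_map(path)
}
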
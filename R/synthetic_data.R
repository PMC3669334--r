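#' Configuration for the paired spike-in simulator
#'
#' Describes two species-like microarray datasets over a shared gene panel:
#' species A with 2 replicates per tissue (human-like) and species B with 3
#' replicates, 4 for muscle (mouse-like). Each gene gets a log-normal
#' baseline intensity shared between the species up to an independent
#' per-species factor; replicate values carry multiplicative log-normal
#' noise at the given coefficient of variation. A configurable number of
#' genes per tissue are spiked: their expected value in exactly one target
#' tissue is multiplied by the fold-change. With probability
#' `conservation_prob` a spiked gene is spiked in both species (same tissue);
#' otherwise in one randomly chosen species only. With probability
#' `platform_dropout_prob` a gene is dropped from one species' annotation
#' entirely, emulating probes present on only one platform.
#'
#' @param n_genes Number of genes (default 5000).
#' @param tissue_names Tissue panel (default [default_tissues()]).
#' @param replicates_a,replicates_b Replicates per tissue, scalar or one
#'   value per tissue (defaults: A = 2 everywhere; B = 3 with 4 for muscle).
#' @param baseline_meanlog,baseline_sdlog Log-normal baseline intensity
#'   parameters (defaults `log(100)` and 1, giving array-like intensities of
#'   roughly 10 to 10000).
#' @param species_sdlog Spread of the per-gene, per-species baseline factor
#'   (default 0.25).
#' @param noise_cv Coefficient of variation of the multiplicative replicate
#'   noise (default 0.1).
#' @param spikes_per_tissue Spiked tissue-specific genes per tissue
#'   (default 5).
#' @param spike_fold Fold-change of spiked genes in their target tissue:
#'   a scalar, or a length-2 range sampled log-uniformly (default 100).
#' @param conservation_prob Probability a spike is present in both species
#'   (default 1).
#' @param platform_dropout_prob Probability a gene is missing from one
#'   species' platform (default 0).
#' @param seed Integer random seed; required, so every dataset is fully
#'   reproducible.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 5000,
                              tissue_names = default_tissues(),
                              replicates_a = 2,
                              replicates_b = ifelse(tissue_names == "muscle", 4, 3),
                              baseline_meanlog = log(100),
                              baseline_sdlog = 1,
                              species_sdlog = 0.25,
                              noise_cv = 0.1,
                              spikes_per_tissue = 5,
                              spike_fold = 100,
                              conservation_prob = 1,
                              platform_dropout_prob = 0,
                              seed) {
  if (missing(seed)) stop("an explicit integer seed is required", call. = FALSE)
  cfg <- list(
    n_genes = as.integer(n_genes), tissue_names = as.character(tissue_names),
    replicates_a = as.integer(rep(replicates_a, length.out = length(tissue_names))),
    replicates_b = as.integer(rep(replicates_b, length.out = length(tissue_names))),
    baseline_meanlog = baseline_meanlog, baseline_sdlog = baseline_sdlog,
    species_sdlog = species_sdlog, noise_cv = noise_cv,
    spikes_per_tissue = as.integer(spikes_per_tissue),
    spike_fold = as.numeric(spike_fold),
    conservation_prob = conservation_prob,
    platform_dropout_prob = platform_dropout_prob,
    seed = as.integer(seed)
  )
  if (cfg$n_genes < 1) stop("n_genes must be >= 1", call. = FALSE)
  if (length(cfg$tissue_names) < 2) stop("need >= 2 tissues", call. = FALSE)
  if (any(cfg$replicates_a < 1) || any(cfg$replicates_b < 1)) {
    stop("replicate counts must be >= 1", call. = FALSE)
  }
  if (cfg$spikes_per_tissue < 0) stop("spikes_per_tissue must be >= 0", call. = FALSE)
  if (any(cfg$spike_fold <= 0) || !length(cfg$spike_fold) %in% 1:2) {
    stop("spike_fold must be a positive scalar or length-2 range", call. = FALSE)
  }
  if (cfg$spikes_per_tissue * length(cfg$tissue_names) > cfg$n_genes) {
    stop("more spikes requested than genes available", call. = FALSE)
  }
  for (p in c("conservation_prob", "platform_dropout_prob")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop(p, " must be in [0, 1]", call. = FALSE)
  }
  if (cfg$noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  structure(cfg, class = "simulation_config")
}

#' Read a simulation configuration from YAML
#'
#' @param path YAML file whose keys are [simulation_config()] arguments.
#' @param seed Seed override; required if the file does not set one.
#' @return A `simulation_config`.
#' @export
read_simulation_config <- function(path, seed = NULL) {
  raw <- yaml::read_yaml(path)
  if (!is.null(seed)) raw$seed <- seed
  do.call(simulation_config, raw)
}

# mean-1 multiplicative log-normal noise at a given CV
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

title_case <- function(x) {
  paste0(toupper(substr(x, 1, 1)), tolower(substr(x, 2, nchar(x))))
}

#' Generate a paired two-species spike-in dataset
#'
#' Draws the shared gene panel, spike assignments and expression values
#' described by the config (see [simulation_config()]) and returns both
#' species' datasets plus the ground-truth manifest. Species A symbols are
#' uppercase and species B symbols title-case, exercising the cross-species
#' symbol normalization. All values are strictly positive and the result is
#' a pure function of the config (including its seed).
#'
#' @param config A [simulation_config()].
#' @return A list with elements `a` and `b` ([expression_dataset()]s) and
#'   `truth`, a tibble with one row per gene and species: `gene_symbol`
#'   (normalized, uppercase), `species` (`"a"`/`"b"`), `target_tissue`
#'   (`NA` for non-spiked genes), `fold_change` (1 for non-spiked genes),
#'   `in_platform`.
#' @export
generate_pair <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
# keep the caller's RNG stream untouched
  old_seed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(cfg$seed)
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)

  ng <- cfg$n_genes
  nt <- length(cfg$tissue_names)
  symbols <- sprintf("GENE%05d", seq_len(ng))
  baseline <- stats::rlnorm(ng, cfg$baseline_meanlog, cfg$baseline_sdlog)

  # spike assignment: disjoint gene sets per tissue
  n_spike <- cfg$spikes_per_tissue * nt
  spike_idx <- sample.int(ng, n_spike)
  spike_tissue <- rep(cfg$tissue_names, each = cfg$spikes_per_tissue)
  draw_fold <- function(n) {
    if (length(cfg$spike_fold) == 1) rep(cfg$spike_fold, n)
    else exp(stats::runif(n, log(cfg$spike_fold[1]), log(cfg$spike_fold[2])))
  }
  conserved <- stats::runif(n_spike) < cfg$conservation_prob
  spike_species <- ifelse(conserved, "both",
                          ifelse(stats::runif(n_spike) < 0.5, "a", "b"))

  target <- setNames(vector("list", 2), c("a", "b"))
  fold <- setNames(vector("list", 2), c("a", "b"))
  for (sp in c("a", "b")) {
    tg <- rep(NA_character_, ng)
    fc <- rep(1, ng)
    in_sp <- spike_species %in% c("both", sp)
    tg[spike_idx[in_sp]] <- spike_tissue[in_sp]
    fc[spike_idx[in_sp]] <- draw_fold(sum(in_sp))
    target[[sp]] <- tg
    fold[[sp]] <- fc
  }

  # platform dropout: gene absent from one randomly chosen species
  dropped <- stats::runif(ng) < cfg$platform_dropout_prob
  drop_side <- ifelse(stats::runif(ng) < 0.5, "a", "b")
  in_platform <- list(a = !(dropped & drop_side == "a"),
                      b = !(dropped & drop_side == "b"))

  build_species <- function(sp) {
    reps <- if (sp == "a") cfg$replicates_a else cfg$replicates_b
    base_sp <- baseline * stats::rlnorm(ng, 0, cfg$species_sdlog)
    cols <- sum(reps)
    vals <- matrix(NA_real_, ng, cols)
    sample_ids <- character(cols)
    j <- 0
    for (ti in seq_len(nt)) {
      tname <- cfg$tissue_names[ti]
      expected <- base_sp * ifelse(!is.na(target[[sp]]) &
                                     target[[sp]] == tname, fold[[sp]], 1)
      for (r in seq_len(reps[ti])) {
        j <- j + 1
        vals[, j] <- expected * rlnorm_cv(ng, cfg$noise_cv)
        sample_ids[j] <- sprintf("GSM%s%03d%02d", toupper(sp), ti, r)
      }
    }
    keep <- in_platform[[sp]]
    syms <- if (sp == "a") symbols else title_case(symbols)
    expression_dataset(vals[keep, , drop = FALSE],
                       gene_symbols = syms[keep],
                       species_label = paste0("synthetic_", sp),
                       feature_ids = paste0(toupper(sp), "_", symbols)[keep],
                       sample_ids = sample_ids)
  }
  a <- build_species("a")
  b <- build_species("b")

  truth <- dplyr::bind_rows(lapply(c("a", "b"), function(sp) {
    tibble::tibble(gene_symbol = symbols, species = sp,
                   target_tissue = target[[sp]], fold_change = fold[[sp]],
                   in_platform = in_platform[[sp]])
  }))
  list(a = a, b = b, truth = truth, config = cfg)
}

#' Build a sample-to-tissue map matching a generated dataset
#'
#' Sample ids produced by [generate_pair()] encode their tissue; this
#' reconstructs the corresponding [tissue_sample_map()].
#'
#' @param dataset A generated [expression_dataset()].
#' @param tissue_names The config's tissue panel, in order.
#' @return A [tissue_sample_map()].
#' @export
synthetic_tissue_map <- function(dataset, tissue_names = default_tissues()) {
  idx <- as.integer(substr(dataset$sample_ids, 5, 7))
  assignments <- lapply(seq_along(tissue_names),
                        function(ti) dataset$sample_ids[idx == ti])
  names(assignments) <- tissue_names
  tissue_sample_map(assignments)
}

#' Write an expression dataset as a GDS-dialect SOFT file
#'
#' Emits the dataset's retained header metadata (or a minimal synthetic
#' header), then the `!dataset_table_begin` block with columns `ID_REF`,
#' `IDENTIFIER` and one per sample. Missing values are written as `null`.
#' Values are printed with full double precision so that
#' [parse_gds_soft()] inverts the file exactly.
#'
#' @param dataset An [expression_dataset()].
#' @param path Output path; a `.gz` suffix writes gzip.
#' @return `path`, invisibly.
#' @export
emit_soft_files <- function(dataset, path) {
  stopifnot(inherits(dataset, "expression_dataset"))
  meta <- dataset$metadata
  if (length(meta) == 0) {
    meta <- c(paste0("^DATASET = synthetic_", dataset$species_label),
              "!dataset_title = synthetic spike-in dataset",
              sprintf("!dataset_sample_count = %d", length(dataset$sample_ids)))
  }
  vals <- dataset$values
  fmt <- sprintf("%.17g", vals)
  fmt[is.na(vals)] <- "null"
  body <- matrix(fmt, nrow = nrow(vals))
  rows <- paste(dataset$feature_ids, dataset$gene_symbols,
                apply(body, 1, paste, collapse = "\t"), sep = "\t")
  header <- paste(c("ID_REF", "IDENTIFIER", dataset$sample_ids), collapse = "\t")
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con), add = TRUE)
  writeLines(c(meta, "!dataset_table_begin", header, rows,
               "!dataset_table_end"), con)
  invisible(path)
}

#' Write a ground-truth manifest as TSV
#'
#' @param truth The `truth` tibble from [generate_pair()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_truth_manifest <- function(truth, path) {
  write_tsv6(truth, path)
  invisible(path)
}
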
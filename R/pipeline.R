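as_dataset <- function(x, species_label) {
  if (inherits(x, "expression_dataset")) return(x)
  parse_gds_soft(x, species_label = species_label)
}

as_tissue_map <- function(x) {
  if (inherits(x, "tissue_sample_map")) return(x)
  read_tissue_map(x)
}

# raw replicate groups (tissue -> values) for one feature of a subset dataset
feature_groups <- function(dataset, map, feature_id) {
  row <- dataset$values[feature_id, ]
  lapply(setNames(map$tissue_names, map$tissue_names), function(t) {
    v <- row[map$assignments[[t]]]
    v[!is.na(v)]
  })
}

# ANOVA + protected-LSD confirmation that `target` is significantly higher
# than every other tissue; NA when replicate counts cannot support it
confirm_feature <- function(dataset, map, feature_id, target, alpha) {
  groups <- feature_groups(dataset, map, feature_id)
  if (any(lengths(groups) < 2)) {
    return(list(anova_p = NA_real_, lsd_max_p = NA_real_, confirmed = NA))
  }
  overall <- one_way_anova(groups)
  if (overall$p_value >= alpha) {
    return(list(anova_p = overall$p_value, lsd_max_p = NA_real_,
                confirmed = FALSE))
  }
  lsd <- posthoc_pairwise(groups, method = "lsd")
  vs_target <- lsd[lsd$group1 == target | lsd$group2 == target, , drop = FALSE]
  # orient estimates as target minus other
  est <- ifelse(vs_target$group1 == target, vs_target$estimate,
                -vs_target$estimate)
  ok <- all(est > 0) && all(vs_target$p_value < alpha)
  list(anova_p = overall$p_value, lsd_max_p = max(vs_target$p_value),
       confirmed = ok)
}

#' Run the full cross-species tissue-specificity pipeline
#'
#' Executes parse, subset, per-tissue averaging, specificity scoring,
#' gene-level ranking, cross-species top-k intersection, single-platform
#' flagging and per-candidate significance testing for every requested
#' target tissue, and optionally writes all tables plus a JSON report.
#'
#' Candidate confirmation follows the protected-LSD protocol: a candidate
#' is `confirmed` when, in both species, its per-gene one-way ANOVA across
#' tissues is significant at `alpha` and Fisher's LSD finds the target
#' tissue significantly higher than every other tissue. When a species has
#' fewer than 2 replicates for some tissue (means-only fixture mode) the
#' confirmation columns are `NA` and all intersected candidates are
#' retained.
#'
#' @param soft_a,soft_b SOFT file paths or [expression_dataset()]s.
#' @param tissues_a,tissues_b Tissue-map paths or [tissue_sample_map()]s;
#'   both maps must cover the same tissue names.
#' @param target `"all"` (default) or a character vector of target tissues.
#' @param top_k Rank cutoff for the cross-species intersection
#'   (default 100).
#' @param ortholog_map Optional two-column ortholog map (data frame or TSV
#'   path).
#' @param alpha Significance level for confirmation (default 0.05).
#' @param species_a,species_b Species labels used in outputs.
#' @param out_dir Optional output directory; created if needed.
#' @return An object of class `run_report`: parameters, and per target
#'   tissue the candidate table (with confirmation columns), the
#'   platform-missing flags, and both species' gene-level ranked tables.
#' @export
run_pipeline <- function(soft_a, soft_b, tissues_a, tissues_b,
                         target = "all", top_k = 100, ortholog_map = NULL,
                         alpha = 0.05, species_a = "species_a",
                         species_b = "species_b", out_dir = NULL) {
  map_a <- as_tissue_map(tissues_a)
  map_b <- as_tissue_map(tissues_b)
  if (!setequal(map_a$tissue_names, map_b$tissue_names)) {
    stop("tissue maps disagree: ",
         paste(setdiff(map_a$tissue_names, map_b$tissue_names), collapse = ", "),
         " vs ",
         paste(setdiff(map_b$tissue_names, map_a$tissue_names), collapse = ", "),
         call. = FALSE)
  }
  targets <- if (identical(target, "all")) map_a$tissue_names else target
  unknown <- setdiff(targets, map_a$tissue_names)
  if (length(unknown)) {
    stop("unknown target tissue(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (is.character(ortholog_map) && length(ortholog_map) == 1) {
    ortholog_map <- read_ortholog_map(ortholog_map)
  }

  digest_of <- function(x) {
    if (is.character(x) && length(x) == 1 && file.exists(x)) {
      unname(tools::md5sum(x))
    } else NA_character_
  }
  params <- list(
    top_k = top_k, alpha = alpha, species_a = species_a,
    species_b = species_b, targets = targets,
    input_digest_a = digest_of(soft_a), input_digest_b = digest_of(soft_b),
    version = as.character(utils::packageVersion("tissuespec"))
  )

  ds_a <- subset_by_tissue_map(as_dataset(soft_a, species_a), map_a)
  ds_b <- subset_by_tissue_map(as_dataset(soft_b, species_b), map_b)
  means_a <- compute_tissue_means(ds_a, map_a)
  means_b <- compute_tissue_means(ds_b, map_b)

  per_tissue <- lapply(setNames(targets, targets), function(tt) {
    ranked_a <- rank_by_specificity(score_specificity(means_a, tt), "gene")
    ranked_b <- rank_by_specificity(score_specificity(means_b, tt), "gene")
    cand <- intersect_top_ranked(ranked_a, ranked_b, k = top_k,
                                 ortholog_map = ortholog_map)
    flags <- flag_platform_missing(ranked_a, ranked_b, k = top_k,
                                   ortholog_map = ortholog_map)
    conf_a <- lapply(cand$symbol_a, function(s) {
      fid <- ranked_a$feature_id[match(s, ranked_a$gene_symbol)]
      confirm_feature(ds_a, map_a, fid, tt, alpha)
    })
    conf_b <- lapply(cand$symbol_b, function(s) {
      fid <- ranked_b$feature_id[match(s, ranked_b$gene_symbol)]
      confirm_feature(ds_b, map_b, fid, tt, alpha)
    })
    cand$anova_p_a <- vapply(conf_a, `[[`, numeric(1), "anova_p")
    cand$anova_p_b <- vapply(conf_b, `[[`, numeric(1), "anova_p")
    cand$lsd_max_p_a <- vapply(conf_a, `[[`, numeric(1), "lsd_max_p")
    cand$lsd_max_p_b <- vapply(conf_b, `[[`, numeric(1), "lsd_max_p")
    ok_a <- vapply(conf_a, `[[`, logical(1), "confirmed")
    ok_b <- vapply(conf_b, `[[`, logical(1), "confirmed")
    cand$confirmed <- ifelse(is.na(ok_a) | is.na(ok_b), NA, ok_a & ok_b)
    list(target_tissue = tt, candidates = cand, platform_flags = flags,
         ranked_a = ranked_a, ranked_b = ranked_b)
  })

  report <- structure(list(parameters = params, per_tissue = per_tissue),
                      class = "run_report")
  if (!is.null(out_dir)) write_run_report(report, out_dir)
  report
}

#' Candidates of a run, across all target tissues
#'
#' @param report A `run_report` from [run_pipeline()].
#' @param confirmed_only Keep only candidates that passed the protected-LSD
#'   confirmation in both species (candidates with `NA` confirmation, e.g.
#'   means-only mode, are kept).
#' @return One tibble of candidate rows across tissues.
#' @export
report_candidates <- function(report, confirmed_only = FALSE) {
  stopifnot(inherits(report, "run_report"))
  out <- dplyr::bind_rows(lapply(report$per_tissue, `[[`, "candidates"))
  if (confirmed_only) out <- out[is.na(out$confirmed) | out$confirmed, , drop = FALSE]
  out
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %s vs %s, k = %d, tissues: %s\n",
              x$parameters$species_a, x$parameters$species_b,
              x$parameters$top_k, paste(x$parameters$targets, collapse = ", ")))
  for (pt in x$per_tissue) {
    cat(sprintf("  %s: %d candidate(s), %d platform flag(s)\n",
                pt$target_tissue, nrow(pt$candidates), nrow(pt$platform_flags)))
  }
  invisible(x)
}

#' Write a run report's tables and JSON summary to disk
#'
#' Writes, per target tissue, both species' gene-level ranked tables, the
#' candidate table and the platform flags as TSV (numerics at 6 significant
#' digits, so identical inputs give byte-identical files), plus a
#' `report.json` with parameters and candidates.
#'
#' @param report A `run_report`.
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly.
#' @export
write_run_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- report$parameters
  for (pt in report$per_tissue) {
    tt <- pt$target_tissue
    write_ranked_table(pt$ranked_a,
                       file.path(out_dir, sprintf("ranked_%s_%s.tsv", p$species_a, tt)))
    write_ranked_table(pt$ranked_b,
                       file.path(out_dir, sprintf("ranked_%s_%s.tsv", p$species_b, tt)))
    write_tsv6(pt$candidates, file.path(out_dir, sprintf("candidates_%s.tsv", tt)))
    write_tsv6(pt$platform_flags,
               file.path(out_dir, sprintf("platform_flags_%s.tsv", tt)))
  }
  json <- list(
    parameters = p,
    candidates = lapply(report$per_tissue, function(pt)
      as.data.frame(pt$candidates)),
    platform_flags = lapply(report$per_tissue, function(pt)
      as.data.frame(pt$platform_flags))
  )
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(out_dir)
}
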
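#' Construct a group summary (means, SEMs, replicate counts)
#'
#' The printed per-gene tables report each tissue as mean ± SEM with a known
#' replicate count. Since `SEM = sd / sqrt(n)`, such a summary carries the
#' full within-group sum of squares and supports an exact one-way ANOVA
#' without the raw replicates (see [anova_from_summary()]).
#'
#' @param labels Group (tissue) labels.
#' @param means,sems Numeric vectors, one value per group; `sems >= 0`.
#' @param n Replicate counts per group, recycled; must be `>= 2` for any
#'   variance-based test.
#' @return An object of class `group_summary`.
#' @export
group_summary <- function(labels, means, sems, n) {
  labels <- as.character(labels)
  n <- as.integer(rep(n, length.out = length(labels)))
  stopifnot(length(means) == length(labels), length(sems) == length(labels))
  if (any(sems < 0, na.rm = TRUE)) stop("SEM must be >= 0", call. = FALSE)
  if (any(n < 1)) stop("replicate counts must be >= 1", call. = FALSE)
  structure(list(labels = labels, means = as.numeric(means),
                 sems = as.numeric(sems), n = n),
            class = "group_summary")
}

#' Summarize raw groups into a group summary
#'
#' @param groups Named list of numeric vectors (one per group).
#' @return A [group_summary()].
#' @export
summarize_groups <- function(groups) {
  if (is.null(names(groups))) names(groups) <- paste0("group", seq_along(groups))
  group_summary(
    labels = names(groups),
    means = vapply(groups, mean, numeric(1)),
    sems = vapply(groups, function(x) stats::sd(x) / sqrt(length(x)), numeric(1)),
    n = lengths(groups)
  )
}

new_test_result <- function(statistic, df1, df2, p_value, method) {
  structure(list(statistic = statistic, df1 = df1, df2 = df2,
                 p_value = p_value, method = method),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s: statistic = %.6g, df = (%s, %s), p = %.4g\n",
              x$method, x$statistic, format(x$df1), format(x$df2), x$p_value))
  invisible(x)
}

check_groups <- function(groups, min_n = 2) {
  if (length(groups) < 2) stop("need at least two groups", call. = FALSE)
  bad <- lengths(groups) < min_n
  if (any(bad)) {
    stop("every group needs n >= ", min_n, "; too small: ",
         paste(if (is.null(names(groups))) which(bad) else names(groups)[bad],
               collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' One-way fixed-effect ANOVA on raw replicate values
#'
#' Classical between/within F test across groups (tissues), the per-gene
#' significance test of the tissue-distribution analysis. When the
#' between-group sum of squares is exactly zero (all group means equal) the
#' result is `F = 0, p = 1` even if the within-group variance is also zero.
#'
#' @param groups Named list of numeric vectors, each of length `>= 2`.
#' @return A `test_result` with the F statistic, numerator/denominator
#'   degrees of freedom, and p-value.
#' @export
one_way_anova <- function(groups) {
  check_groups(groups)
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  k <- length(groups)
  df1 <- k - 1L
  df2 <- length(y) - k
  gm <- tapply(y, g, mean)
  ssb <- sum(lengths(groups) * (gm - mean(y))^2)
  if (ssb <= 0 || isTRUE(all.equal(ssb, 0))) {
    return(new_test_result(0, df1, df2, 1, "one-way ANOVA"))
  }
  tab <- stats::anova(stats::lm(y ~ g))
  new_test_result(unname(tab[["F value"]][1]), df1, df2,
                  unname(tab[["Pr(>F)"]][1]), "one-way ANOVA")
}

#' One-way ANOVA reconstructed from a mean/SEM summary
#'
#' Rebuilds the within-group sum of squares from `sd_i = SEM_i * sqrt(n_i)`
#' and the between-group sum of squares from the group means, giving exactly
#' the F test that [one_way_anova()] would produce from the raw replicates
#' the summary was computed from. This makes published mean ± SEM tables
#' first-class test inputs.
#'
#' @param summary A [group_summary()] with every `n >= 2`.
#' @return A `test_result`.
#' @export
anova_from_summary <- function(summary) {
  stopifnot(inherits(summary, "group_summary"))
  if (any(summary$n < 2)) {
    stop("every group needs n >= 2 for a variance estimate; too small: ",
         paste(summary$labels[summary$n < 2], collapse = ", "), call. = FALSE)
  }
  k <- length(summary$labels)
  if (k < 2) stop("need at least two groups", call. = FALSE)
  N <- sum(summary$n)
  sds <- summary$sems * sqrt(summary$n)
  ssw <- sum((summary$n - 1) * sds^2)
  grand <- sum(summary$n * summary$means) / N
  ssb <- sum(summary$n * (summary$means - grand)^2)
  df1 <- k - 1L
  df2 <- N - k
  if (ssb <= 0 || isTRUE(all.equal(ssb, 0))) {
    return(new_test_result(0, df1, df2, 1, "one-way ANOVA (from summary)"))
  }
  f <- (ssb / df1) / (ssw / df2)
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  new_test_result(f, df1, df2, p, "one-way ANOVA (from summary)")
}

as_group_summary <- function(data) {
  if (inherits(data, "group_summary")) return(data)
  if (is.list(data)) return(summarize_groups(data))
  stop("expected a list of raw groups or a group_summary", call. = FALSE)
}

#' Pairwise post-hoc comparisons after one-way ANOVA
#'
#' Both methods use the ANOVA's pooled mean squared error and its residual
#' degrees of freedom for every pair:
#' \describe{
#'   \item{`lsd`}{Fisher's (protected) least significant difference:
#'     pairwise t statistics `(m_i - m_j) / sqrt(MSE (1/n_i + 1/n_j))` with
#'     two-sided p from the t distribution on the pooled df. "Protected"
#'     means it should only be read after a significant overall F; the
#'     overall ANOVA is attached as attribute `"anova"`.}
#'   \item{`tukey`}{Tukey's honest significant difference: the same
#'     statistics referred to the studentized range,
#'     `p = P(q >= sqrt(2) |t|)` with `k` groups and the pooled df.}
#' }
#'
#' @param data Named list of raw groups, or a [group_summary()].
#' @param method `"lsd"` or `"tukey"`.
#' @return A tibble with one row per unordered pair: `group1`, `group2`,
#'   `estimate` (mean difference), `statistic`, `df`, `p_value`, `method`;
#'   the overall `test_result` is attached as attribute `"anova"`.
#' @export
posthoc_pairwise <- function(data, method = c("lsd", "tukey")) {
  method <- match.arg(method)
  gs <- as_group_summary(data)
  overall <- anova_from_summary(gs)
  k <- length(gs$labels)
  N <- sum(gs$n)
  df <- N - k
  sds <- gs$sems * sqrt(gs$n)
  mse <- sum((gs$n - 1) * sds^2) / df

  pairs <- utils::combn(k, 2)
  i <- pairs[1, ]; j <- pairs[2, ]
  est <- gs$means[i] - gs$means[j]
  se <- sqrt(mse * (1 / gs$n[i] + 1 / gs$n[j]))
  tstat <- ifelse(se == 0, ifelse(est == 0, 0, sign(est) * Inf), est / se)
  p <- if (method == "lsd") {
    2 * stats::pt(-abs(tstat), df)
  } else {
    stats::ptukey(sqrt(2) * abs(tstat), nmeans = k, df = df,
                  lower.tail = FALSE)
  }
  p[tstat == 0] <- 1
  out <- tibble::tibble(
    group1 = gs$labels[i], group2 = gs$labels[j],
    estimate = est, statistic = tstat, df = df, p_value = p,
    method = if (method == "lsd") "Fisher LSD" else "Tukey HSD"
  )
  attr(out, "anova") <- overall
  out
}

#' Two-sample t test
#'
#' Two-sided Student's t test, pooled-variance by default or Welch when
#' `welch = TRUE` (Welch–Satterthwaite degrees of freedom).
#'
#' @param a,b Numeric vectors of raw values, each of length `>= 2`.
#' @param welch Use the unequal-variance form.
#' @return A `test_result` (for the t test `df1` is the single df and `df2`
#'   is `NA`).
#' @export
student_t_test <- function(a, b, welch = FALSE) {
  check_groups(list(a = a, b = b))
  method <- if (welch) "Welch t test" else "Student t test"
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    # zero-variance data: t.test refuses; define the limit directly
    df <- length(a) + length(b) - 2
    d <- mean(a) - mean(b)
    if (d == 0) return(new_test_result(0, df, NA_real_, 1, method))
    return(new_test_result(sign(d) * Inf, df, NA_real_, 0, method))
  }
  ht <- stats::t.test(a, b, var.equal = !welch)
  new_test_result(unname(ht$statistic), unname(ht$parameter), NA_real_,
                  ht$p.value, method)
}

#' Normalize every gene to a reference (housekeeping) gene
#'
#' Divides each sample's column by that sample's reference-gene value, the
#' standard cyclophilin-style relative-expression transform. The reference
#' gene is located by case-insensitive symbol match; if several probes carry
#' the symbol, their per-sample arithmetic mean is the reference value. The
#' reference must be present, non-missing and strictly positive in every
#' sample. The operation is idempotent: the reference row becomes 1
#' everywhere, so renormalizing changes nothing.
#'
#' @param dataset An [expression_dataset()].
#' @param reference_symbol Gene symbol of the reference gene.
#' @return A new [expression_dataset()] of relative expression values.
#' @export
normalize_to_reference <- function(dataset, reference_symbol) {
  stopifnot(inherits(dataset, "expression_dataset"))
  hit <- toupper(dataset$gene_symbols) == toupper(reference_symbol)
  if (!any(hit)) {
    stop("reference gene '", reference_symbol, "' not found in annotation",
         call. = FALSE)
  }
  ref <- colMeans(dataset$values[hit, , drop = FALSE])
  bad <- is.na(ref) | ref <= 0
  if (any(bad)) {
    stop("reference gene '", reference_symbol,
         "' is missing or nonpositive in sample(s): ",
         paste(dataset$sample_ids[bad], collapse = ", "), call. = FALSE)
  }
  expression_dataset(sweep(dataset$values, 2, ref, "/"),
                     gene_symbols = dataset$gene_symbols,
                     species_label = dataset$species_label,
                     feature_ids = dataset$feature_ids,
                     sample_ids = dataset$sample_ids,
                     metadata = dataset$metadata)
}
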
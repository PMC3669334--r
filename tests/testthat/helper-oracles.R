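# Independent oracles, deliberately written as plain loops so they share no
# code path with the package implementation.

# specificity scores computed feature-by-feature, straight from the method's
# definition: ratios to the target mean, averaged; and target over mean of
# other means
naive_specificity <- function(means, target) {
  tissues <- colnames(means)
  others <- setdiff(tissues, target)
  score_i <- score_v <- rep(NA_real_, nrow(means))
  for (f in seq_len(nrow(means))) {
    mt <- means[f, target]
    mo <- means[f, others]
    if (is.na(mt) || mt <= 0 || anyNA(mo)) next
    ratios <- numeric(0)
    for (t in others) ratios <- c(ratios, means[f, t] / mt)
    score_i[f] <- sum(ratios) / length(ratios)
    score_v[f] <- mt / (sum(mo) / length(mo))
  }
  list(score_i = score_i, score_v = score_v)
}

# brute-force sums of squares for one-way ANOVA
oracle_anova <- function(groups) {
  all_y <- unlist(groups)
  grand <- mean(all_y)
  ssb <- 0
  ssw <- 0
  for (g in groups) {
    ssb <- ssb + length(g) * (mean(g) - grand)^2
    for (y in g) ssw <- ssw + (y - mean(g))^2
  }
  k <- length(groups)
  n <- length(all_y)
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  list(f = f, df1 = k - 1, df2 = n - k,
       p = pf(f, k - 1, n - k, lower.tail = FALSE))
}

# Welch-Satterthwaite degrees of freedom
oracle_welch_df <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
}

random_means <- function(n_features, tissues = default_tissues()) {
  matrix(rlnorm(n_features * length(tissues), log(100), 1),
         nrow = n_features,
         dimnames = list(sprintf("F%04d", seq_len(n_features)), tissues))
}

# a tiny two-tissue dataset used across io tests
tiny_dataset <- function() {
  vals <- matrix(c(10, 20, 30, 40, 50, 60), nrow = 3, byrow = TRUE,
                 dimnames = list(c("p1", "p2", "p3"), c("GSM1", "GSM2")))
  expression_dataset(vals, gene_symbols = c("GA", "GB", ""),
                     species_label = "test")
}

tiny_soft_text <- function() {
  c("^DATASET = toy",
    "!dataset_title = toy dataset",
    "!dataset_table_begin",
    "ID_REF\tIDENTIFIER\tGSM1\tGSM2",
    "p1\tGA\t10\t20",
    "p2\tGB\t30\tnull",
    "p3\t--\t50\t60",
    "!dataset_table_end")
}
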
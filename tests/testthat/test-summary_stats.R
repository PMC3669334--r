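test_that("one-way ANOVA matches the F = t^2 identity and the SS oracle", {
  g <- list(a = c(9, 10, 11), b = c(19, 20, 21))
  res <- one_way_anova(g)
  expect_equal(res$statistic, 150, tolerance = 1e-10)
  tt <- student_t_test(g$a, g$b)
  expect_equal(res$statistic, tt$statistic^2, tolerance = 1e-10)
  expect_equal(res$df1, 1L)
  expect_equal(res$df2, 4L)

  set.seed(11)
  for (i in 1:10) {
    groups <- lapply(sample(2:5, 3, replace = TRUE) + 1, rnorm, mean = 5)
    res <- one_way_anova(groups)
    orc <- oracle_anova(groups)
    expect_equal(res$statistic, orc$f, tolerance = 1e-10)
    expect_equal(res$p_value, orc$p, tolerance = 1e-10)
    expect_equal(res$df2, orc$df2)
  }
})

test_that("degenerate ANOVA inputs behave: identical groups, tiny groups", {
  expect_equal(one_way_anova(list(c(5, 5), c(5, 5)))$p_value, 1)
  expect_equal(one_way_anova(list(c(5, 5), c(5, 5)))$statistic, 0)
  expect_error(one_way_anova(list(c(1, 2), 3)), "n >= 2")
  expect_error(one_way_anova(list(c(1, 2))), "two groups")
})

test_that("summary ANOVA reproduces raw-data ANOVA exactly", {
  g <- list(a = c(9, 10, 11), b = c(19, 20, 21))
  res <- anova_from_summary(summarize_groups(g))
  expect_equal(res$statistic, 150, tolerance = 1e-9)

  gs <- group_summary(c("a", "b"), means = c(10, 20), sems = c(0.5774, 0.5774),
                      n = 3)
  expect_equal(anova_from_summary(gs)$statistic, 150, tolerance = 1e-3)

  set.seed(12)
  for (i in 1:25) {
    groups <- lapply(sample(2:6, 4, replace = TRUE) + 1, rnorm, mean = 3, sd = 2)
    raw <- one_way_anova(groups)
    summ <- anova_from_summary(summarize_groups(groups))
    expect_equal(summ$statistic, raw$statistic, tolerance = 1e-9)
    expect_equal(summ$p_value, raw$p_value, tolerance = 1e-9)
  }

  flat <- group_summary(c("a", "b"), c(7, 7), c(1, 2), n = 3)
  expect_equal(anova_from_summary(flat)$statistic, 0)
  expect_equal(anova_from_summary(flat)$p_value, 1)
  expect_error(anova_from_summary(group_summary("a", 1, 0.5, n = 1)), "n >= 2")
})

test_that("the printed mouse-liver AMDHD1 summary is significant far below 1e-4", {
  res <- anova_from_summary(printed_gene_summary("mouse", "liver", "AMDHD1",
                                                 n = 3))
  expect_lt(res$p_value, 1e-4)
})

test_that("LSD reduces to the pooled t test for two groups", {
  set.seed(13)
  a <- rnorm(4); b <- rnorm(5, 1)
  lsd <- posthoc_pairwise(list(a = a, b = b), "lsd")
  tt <- student_t_test(a, b)
  expect_equal(lsd$p_value, tt$p_value, tolerance = 1e-12)
  expect_equal(abs(lsd$statistic), abs(tt$statistic), tolerance = 1e-12)
  tk <- posthoc_pairwise(list(a = a, b = b), "tukey")
  expect_equal(tk$p_value, tt$p_value, tolerance = 1e-9)
})

test_that("identical groups give all pairwise p = 1", {
  g <- list(a = c(5, 6), b = c(5, 6), c = c(5, 6))
  for (m in c("lsd", "tukey")) {
    ph <- posthoc_pairwise(g, m)
    expect_equal(ph$p_value, rep(1, 3))
  }
})

test_that("Tukey p-values match TukeyHSD on random unbalanced groups", {
  set.seed(14)
  for (i in 1:5) {
    groups <- lapply(sample(3:6, 3, replace = TRUE), rnorm, mean = i)
    names(groups) <- c("g1", "g2", "g3")
    ours <- posthoc_pairwise(groups, "tukey")
    y <- unlist(groups)
    f <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
    ref <- TukeyHSD(aov(y ~ f))$f
    key_ours <- paste(ours$group2, ours$group1, sep = "-")
    expect_equal(ours$p_value[match(rownames(ref), key_ours)],
                 unname(ref[, "p adj"]), tolerance = 1e-6)
  }
})

test_that("posthoc accepts a mean/SEM summary as input", {
  g <- list(a = c(9, 10, 11), b = c(19, 20, 21), c = c(14, 15, 16))
  expect_equal(posthoc_pairwise(summarize_groups(g), "lsd")$p_value,
               posthoc_pairwise(g, "lsd")$p_value, tolerance = 1e-12)
})

test_that("t test reproduces the textbook example and the Welch df formula", {
  res <- student_t_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(abs(res$statistic), 3.674, tolerance = 1e-3)
  expect_equal(res$df1, 4)
  expect_equal(res$p_value, 0.0214, tolerance = 1e-2)

  expect_equal(student_t_test(c(1, 2), c(1, 2))$p_value, 1)

  set.seed(15)
  a <- rnorm(5, sd = 1); b <- rnorm(12, sd = 4)
  wres <- student_t_test(a, b, welch = TRUE)
  expect_equal(wres$df1, oracle_welch_df(a, b), tolerance = 1e-9)
  expect_error(student_t_test(1, c(1, 2)), "n >= 2")
})

test_that("reference-gene normalization divides by the per-sample reference", {
  vals <- matrix(c(50, 100,
                   25, 50), nrow = 2, byrow = TRUE,
                 dimnames = list(c("p_gene", "p_ref"), c("s1", "s2")))
  ds <- expression_dataset(vals, gene_symbols = c("MYGENE", "CYC"),
                           species_label = "t")
  norm <- normalize_to_reference(ds, "cyc")  # case-insensitive
  expect_equal(unname(norm$values["p_gene", ]), c(2, 2))
  expect_equal(unname(norm$values["p_ref", ]), c(1, 1))

  # idempotent and invariant to per-sample rescaling
  again <- normalize_to_reference(norm, "CYC")
  expect_equal(again$values, norm$values)
  scaled <- ds
  scaled$values[, "s1"] <- scaled$values[, "s1"] * 7
  expect_equal(normalize_to_reference(scaled, "CYC")$values, norm$values)
})

test_that("normalization errors name the offending samples", {
  vals <- matrix(c(50, 100, 0, 50), nrow = 2, byrow = TRUE,
                 dimnames = list(c("p_gene", "p_ref"), c("s1", "s2")))
  ds <- expression_dataset(vals, gene_symbols = c("MYGENE", "CYC"),
                           species_label = "t")
  expect_error(normalize_to_reference(ds, "CYC"), "s1")
  expect_error(normalize_to_reference(ds, "NOPE"), "not found")
})
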
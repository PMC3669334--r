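test_that("tissue means average non-missing replicates and count them", {
  vals <- matrix(c(10, 20, 30,
                   10, NA, 20,
                   NA, NA, NA), nrow = 3, byrow = TRUE,
                 dimnames = list(c("p1", "p2", "p3"), c("s1", "s2", "s3")))
  ds <- expression_dataset(vals, species_label = "t")
  map <- tissue_sample_map(list(kidney = c("s1", "s2", "s3")))
  tm <- compute_tissue_means(ds, map)
  expect_equal(unname(tm$means[, "kidney"]), c(20, 15, NA))
  expect_equal(unname(tm$n_replicates[, "kidney"]), c(3L, 2L, 0L))
})

test_that("human kidney FXYD2 replicates reconstructed from the printed
           summary average to the printed mean", {
  # n = 2 and SEM = |a - b| / 2, so the pair mean +/- SEM recreates the samples
  samples <- c(12125141, 11579359)
  expect_equal(mean(samples), 11852250)
  ds <- expression_dataset(matrix(samples, 1, 2,
                                  dimnames = list("FXYD2_probe", c("GSM18955", "GSM18956"))),
                           gene_symbols = "FXYD2", species_label = "human")
  tm <- compute_tissue_means(ds, tissue_sample_map(list(kidney = c("GSM18955", "GSM18956"))))
  expect_equal(unname(tm$means["FXYD2_probe", "kidney"]), 11852250)
  tab <- printed_tables("human", "kidney")
  expect_equal(tab$mean[tab$gene_symbol == "FXYD2" & tab$tissue == "kidney"],
               11852250)
})

test_that("worked examples from the mouse tables score as hand-computed", {
  kid <- score_specificity(load_printed_table("mouse", "kidney"), "kidney")
  fx <- kid[kid$gene_symbol == "FXYD2", ]
  expect_equal(fx$score_v, 9786 / mean(c(76, 99, 113, 106, 215)),
               tolerance = 1e-12)
  expect_equal(fx$score_v, 80.345, tolerance = 1e-4)
  expect_equal(fx$score_i, 0.0124463, tolerance = 1e-5)
  expect_equal(fx$ratio_kidney, 1)

  adi <- score_specificity(load_printed_table("mouse", "adipose"), "adipose")
  ac <- adi[adi$gene_symbol == "ACVR1C", ]
  expect_equal(ac$score_v, 776 / mean(c(58, 61, 63, 60, 68)), tolerance = 1e-12)
  expect_equal(ac$score_v, 12.516, tolerance = 1e-4)
})

test_that("equal means across tissues give unit scores", {
  m <- matrix(42, 3, 6, dimnames = list(paste0("f", 1:3), default_tissues()))
  sc <- score_specificity(tissue_mean_matrix(m), "kidney")
  expect_equal(sc$score_i, rep(1, 3))
  expect_equal(sc$score_v, rep(1, 3))
})

test_that("degenerate features are excluded with a reason, not scored", {
  m <- random_means(4)
  m[1, "kidney"] <- 0
  m[2, "liver"] <- NA
  m[3, "kidney"] <- NA
  sc <- score_specificity(tissue_mean_matrix(m), "kidney")
  expect_equal(sc$excluded_reason,
               c("nonpositive target mean", "undefined non-target mean",
                 "undefined target mean", ""))
  expect_true(all(is.na(sc$score_i[1:3])))
  expect_error(score_specificity(tissue_mean_matrix(m), "brain"),
               "unknown target")
})

test_that("ranking sorts ascending score_i, breaks ties by symbol then id,
           and parks excluded features last", {
  m <- random_means(2)
  sc <- score_specificity(tissue_mean_matrix(m), "kidney")
  sc$score_i <- c(0.5, 0.1)
  sc$gene_symbol <- c("g2", "g1")
  r <- rank_by_specificity(sc)
  expect_equal(r$gene_symbol, c("g1", "g2"))
  expect_equal(r$rank, 1:2)

  # ties: same score, symbol decides, then feature id
  m4 <- random_means(4)
  sc4 <- score_specificity(tissue_mean_matrix(m4), "kidney")
  sc4$score_i <- 0.2
  sc4$gene_symbol <- c("B", "A", "A", "C")
  sc4$feature_id <- c("z", "y", "x", "w")
  r4 <- rank_by_specificity(sc4)
  expect_equal(r4$feature_id, c("x", "y", "z", "w"))

  # excluded features come after every scored one
  m5 <- random_means(3)
  m5[2, "kidney"] <- NA
  r5 <- rank_by_specificity(score_specificity(tissue_mean_matrix(m5), "kidney"))
  expect_equal(r5$excluded_reason[3], "undefined target mean")
  expect_error(rank_by_specificity(rbind(
    score_specificity(tissue_mean_matrix(m5), "kidney"),
    score_specificity(tissue_mean_matrix(m5), "liver"))),
    "mix target tissues")
})

test_that("gene-level ranking keeps each symbol's best probe", {
  m <- random_means(5)
  sc <- score_specificity(tissue_mean_matrix(m), "kidney")
  sc$score_i <- c(0.3, 0.1, 0.2, 0.15, 0.05)
  sc$gene_symbol <- c("G1", "G1", "G2", "", "")
  r <- rank_by_specificity(sc, "gene")
  expect_equal(nrow(r), 4)                    # G1 collapsed, blanks kept
  expect_equal(r$score_i[r$gene_symbol == "G1"], 0.1)
  expect_equal(r$rank, 1:4)
})

test_that("the mouse kidney table ranks by descending score_v with FXYD2 first", {
  tm <- load_printed_table("mouse", "kidney")
  r <- rank_by_specificity(score_specificity(tm, "kidney"), "gene")
  oracle <- naive_specificity(tm$means, "kidney")
  expect_equal(r$gene_symbol[1:2],
               rownames(tm$means)[order(-oracle$score_v)][1:2])
  expect_equal(r$gene_symbol[1:2], c("FXYD2", "SLC34A1"))
})

test_that("score_v and score_i are exact reciprocals and induce the same order", {
  set.seed(41)
  for (i in 1:20) {
    m <- random_means(50)
    sc <- score_specificity(tissue_mean_matrix(m), sample(default_tissues(), 1))
    expect_true(all(abs(sc$score_v * sc$score_i - 1) < 1e-9))
    expect_identical(order(sc$score_i, sc$feature_id),
                     order(-sc$score_v, sc$feature_id))
  }
})

test_that("scores are invariant to global scaling and replicate shuffling,
           and monotone in the target mean", {
  set.seed(42)
  m <- random_means(30)
  sc <- score_specificity(tissue_mean_matrix(m), "liver")
  sc_scaled <- score_specificity(tissue_mean_matrix(m * 37.5), "liver")
  expect_equal(sc$score_i, sc_scaled$score_i, tolerance = 1e-12)
  expect_equal(sc$score_v, sc_scaled$score_v, tolerance = 1e-12)

  # replicate permutation within a tissue leaves means, hence scores, unchanged
  vals <- matrix(rlnorm(20 * 6), 20, 6,
                 dimnames = list(sprintf("f%02d", 1:20), paste0("s", 1:6)))
  ds <- expression_dataset(vals, species_label = "t")
  map1 <- tissue_sample_map(list(kidney = c("s1", "s2", "s3"),
                                 liver = c("s4", "s5", "s6")))
  map2 <- tissue_sample_map(list(kidney = c("s3", "s1", "s2"),
                                 liver = c("s6", "s4", "s5")))
  expect_equal(compute_tissue_means(ds, map1)$means,
               compute_tissue_means(ds, map2)$means)

  # raising only the target mean strictly improves specificity
  m2 <- m
  m2[, "liver"] <- m2[, "liver"] * 2
  sc2 <- score_specificity(tissue_mean_matrix(m2), "liver")
  expect_true(all(sc2$score_i < sc$score_i))
  expect_true(all(sc2$score_v > sc$score_v))
})

test_that("scores match the naive from-definition oracle to 1e-12 relative", {
  set.seed(43)
  for (i in 1:10) {
    m <- random_means(50)
    target <- sample(default_tissues(), 1)
    sc <- score_specificity(tissue_mean_matrix(m), target)
    oracle <- naive_specificity(m, target)
    expect_equal(sc$score_i, oracle$score_i, tolerance = 1e-12)
    expect_equal(sc$score_v, oracle$score_v, tolerance = 1e-12)
  }
})
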
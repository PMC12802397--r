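test_that("CPM normalization is exact and guards degenerate input", {
  man <- make_manifest(1, 2, 0)
  cm <- count_matrix(matrix(c(7L, 3L, 100L, 5L), nrow = 2,
                            dimnames = list(man$element_id, c("a", "b"))), man)
  norm0 <- normalize_counts(cm, pseudocount = 0)
  expect_equal(colSums(norm0$freq), c(a = 1e6, b = 1e6))
  expect_equal(unname(norm0$freq[, "a"]), c(7e5, 3e5))

  two <- count_matrix(matrix(c(1L, 3L), nrow = 2,
                             dimnames = list(man$element_id, "s")), man)
  expect_equal(unname(normalize_counts(two, pseudocount = 0)$freq[, "s"]),
               c(2.5e5, 7.5e5))
  # pseudocount moves a zero count off zero
  z <- count_matrix(matrix(c(0L, 4L), nrow = 2,
                           dimnames = list(man$element_id, "s")), man)
  expect_gt(normalize_counts(z, pseudocount = 1)$freq[1, "s"], 0)

  zz <- count_matrix(matrix(c(0L, 0L), nrow = 2,
                            dimnames = list(man$element_id, "bad")), man)
  expect_error(normalize_counts(zz), "bad")
})

test_that("sgRNA log2FC has the documented orientation and arithmetic", {
  man <- make_manifest(1, 3, 0)
  # equal column totals: element 1 equal in both bins, element 2 at 4:1
  # low:high, element 3 the mirror image
  counts <- matrix(c(100L, 20L, 80L, 100L, 80L, 20L), nrow = 3,
                   dimnames = list(man$element_id, c("hi", "lo")))
  cm <- count_matrix(counts, man)
  sheet <- sample_sheet(data.frame(
    sample_id = c("hi", "lo"), screen_id = "s", arm = "facs",
    role = c("high_bin", "low_bin")))
  norm <- normalize_counts(cm, pseudocount = 0)
  sg <- sgrna_log2fc(norm, sheet, "s", "facs", man)
  expect_equal(sg$log2fc[1], 0)
  expect_equal(sg$log2fc[2], 2)   # depleted from responder bin -> positive
  expect_equal(sg$log2fc[3], -2)

  bad_sheet <- sample_sheet(data.frame(
    sample_id = c("d0", "end"), screen_id = "surv", arm = "survival",
    role = c("day0", "endpoint")))
  expect_error(sgrna_log2fc(norm, bad_sheet, "s", "facs", man), "no samples")
})

test_that("vectorized rank-sum p-values match wilcox.test on untied and tied data", {
  set.seed(42)
  for (i in 1:60) {
    n <- sample(2:8, 1); m <- sample(10:60, 1)
    x <- rnorm(n); y <- rnorm(m)
    u <- sum(outer(x, y, ">"))
    expect_equal(sortscreen:::rank_sum_p(u, n, m, FALSE, 0),
                 wilcox.test(x, y, exact = TRUE)$p.value, tolerance = 1e-12)
    x2 <- sample(seq(0, 2, 0.25), n, TRUE); y2 <- sample(seq(0, 2, 0.25), m, TRUE)
    u2 <- sum(outer(x2, y2, ">")) + 0.5 * sum(outer(x2, y2, "=="))
    tt <- table(c(x2, y2))
    expect_equal(sortscreen:::rank_sum_p(u2, n, m, TRUE, sum(tt^3 - tt)),
                 suppressWarnings(wilcox.test(x2, y2, exact = FALSE,
                                              correct = TRUE)$p.value),
                 tolerance = 1e-9)
  }
})

test_that("gene statistics satisfy the phenotype-score and exchangeability identities", {
  scr <- tiny_screen(n_genes = 60, n_ntc = 30, seed = 7)
  g <- call_screen(scr$sim$counts, scr$sim$sheet, scr$man, seed = 11)
  expect_equal(g$phenotype_score, g$effect * (-log10(g$p_value)))
  expect_true(all(g$fdr >= 0 & g$fdr <= 1))
  expect_true(all(sign(g$phenotype_score) == sign(g$effect) |
                    g$phenotype_score == 0))
  # a gene whose sgRNA values are drawn from the NTC values is unremarkable
  norm <- normalize_counts(scr$sim$counts)
  sg <- sgrna_log2fc(norm, scr$sim$sheet, "sim", "facs", scr$man)
  ntc_idx <- which(sg$category == "non_targeting")
  sg2 <- sg
  sg2$log2fc[sg2$gene == "g0001"] <- sg$log2fc[ntc_idx[1:5]]
  gs2 <- gene_stats(sg2, seed = 11)
  expect_gt(gs2$p_value[gs2$gene == "g0001"], 0.3)
  expect_lt(abs(gs2$phenotype_score[gs2$gene == "g0001"]), 0.5)
})

test_that("flipping bin labels negates every effect and phenotype score exactly", {
  scr <- tiny_screen(n_genes = 50, n_ntc = 25, seed = 13,
                     effects = setNames(c(0.2, 4), c("g0001", "g0002")))
  sheet_flipped <- scr$sim$sheet
  sheet_flipped$role[sheet_flipped$role == "high_bin"] <- "tmp"
  sheet_flipped$role[sheet_flipped$role == "low_bin"] <- "high_bin"
  sheet_flipped$role[sheet_flipped$role == "tmp"] <- "low_bin"
  sheet_flipped <- sample_sheet(as.data.frame(sheet_flipped))
  g1 <- call_screen(scr$sim$counts, scr$sim$sheet, scr$man, seed = 3)
  g2 <- call_screen(scr$sim$counts, sheet_flipped, scr$man, seed = 3)
  expect_equal(g2$effect, -g1$effect)
  expect_equal(g2$phenotype_score, -g1$phenotype_score)
  expect_equal(g2$fdr, g1$fdr)
})

test_that("quasi-gene resampling is seed-deterministic", {
  scr <- tiny_screen(n_genes = 40, n_ntc = 20, seed = 17)
  g1 <- call_screen(scr$sim$counts, scr$sim$sheet, scr$man, seed = 5)
  g2 <- call_screen(scr$sim$counts, scr$sim$sheet, scr$man, seed = 5)
  expect_identical(g1$fdr, g2$fdr)
  expect_identical(attr(g1, "quasi"), attr(g2, "quasi"))
  g3 <- call_screen(scr$sim$counts, scr$sim$sheet, scr$man, seed = 6)
  expect_false(identical(attr(g1, "quasi")$phenotype_score,
                         attr(g3, "quasi")$phenotype_score))
})

test_that("empirical FDR is computed per direction, capped and monotone", {
  real <- c(10, 5, 2, 1, 0.5, -0.5, -1, -6)
  quasi <- c(0.4, 0.3, 0.2, 0.1, -0.1, -0.2, -0.3, -3)
  fdr <- empirical_fdr(real, quasi)
  # score 10: no quasi >= 10 -> (0 + 1)/1 = 1, monotonized by min over the
  # less extreme positive thresholds: at t=0.5, 4 quasi >= 0.5-eps? none;
  # raw there = (0*1 + 1)/5 = 0.2
  expect_equal(fdr[real == 10], 0.2)
  expect_true(all(fdr >= 0 & fdr <= 1))
  for (dir in list(real >= 0, real < 0)) {
    sub <- order(abs(real[dir]), decreasing = TRUE)
    expect_true(all(diff(fdr[dir][sub]) >= 0))
  }
  # a real score inside the quasi bulk gets FDR 1
  expect_equal(unname(empirical_fdr(c(0.05, 8), c(1, -1, 0.5, -0.5, 0.2))[1]), 1)
})

test_that("hit classification and ranking follow thresholds and tie-breaks", {
  g <- data.frame(gene = c("a", "b", "c", "d"),
                  effect = c(1, -2, 0.5, 1),
                  p_value = c(0.001, 0.001, 0.2, 0.05),
                  phenotype_score = c(3, -6, 0.35, 1.3),
                  fdr = c(0.03, 0.07, 0.5, 0.2))
  cls <- classify_hits(g)
  expect_equal(cls$hit_class,
               c("strong_positive_regulator", "weak_negative_regulator",
                 "none", "none"))
  r <- rank_by_phenotype(data.frame(gene = c("x", "y", "z"),
                                    phenotype_score = c(3, 1, 2)))
  expect_equal(r$gene, c("x", "z", "y"))
  r2 <- rank_by_phenotype(data.frame(gene = c("b", "a"),
                                     phenotype_score = c(1, 1)))
  expect_equal(r2$gene, c("a", "b"))
})

test_that("gene_stats refuses null-free or under-powered input", {
  scr <- tiny_screen(n_genes = 10, n_ntc = 5, seed = 19)
  norm <- normalize_counts(scr$sim$counts)
  sg <- sgrna_log2fc(norm, scr$sim$sheet, "sim", "facs", scr$man)
  no_ntc <- sg[sg$category == "targeting", ]
  class(no_ntc) <- class(sg)
  expect_error(gene_stats(no_ntc), "non-targeting")
  one_guide <- sg[c(which(sg$gene == "g0001")[1],
                    which(sg$category == "non_targeting")), ]
  class(one_guide) <- class(sg)
  expect_error(gene_stats(one_guide), "fewer than 2")
})
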
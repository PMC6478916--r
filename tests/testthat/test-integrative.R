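# Differential expression/methylation thresholds, starburst integration,
# FET-based GO analysis and the alteration landscape.

test_that("identical groups produce no significant expression calls", {
  set.seed(41)
  counts <- matrix(rnbinom(200 * 12, mu = 100, size = 10), 200, 12,
                   dimnames = list(paste0("g", 1:200), paste0("s", 1:12)))
  groups <- rep(c("A", "B"), each = 6)
  res <- diff_expression(counts, groups, mode = "count")
  expect_equal(sum(res$significant), 0L)
})

test_that("count-mode DE recovers a 4-fold spike with controlled false positives", {
  sens <- numeric(5); fpr <- numeric(5)
  set.seed(42)
  for (r in 1:5) {
    n_genes <- 500
    counts <- matrix(rnbinom(n_genes * 20, mu = 100, size = 8), n_genes, 20,
                     dimnames = list(paste0("g", 1:n_genes), paste0("s", 1:20)))
    spiked <- paste0("g", 1:50)
    counts[spiked, 11:20] <- matrix(
      rnbinom(50 * 10, mu = 400, size = 8), 50, 10)
    res <- diff_expression(counts, rep(c("A", "B"), each = 10), mode = "count")
    pos <- res$gene[res$significant]
    sens[r] <- mean(spiked %in% pos)
    fpr[r] <- mean(setdiff(res$gene, spiked) %in% pos)
  }
  expect_gte(median(sens), 45 / 50)
  expect_lte(median(fpr), 0.05)
})

test_that("fold-change threshold is strict at 1.5", {
  base <- c(10, 11, 12, 13, 14, 15)
  mat <- rbind(exact = c(base, base * 1.5),
               above = c(base, base * 1.6))
  colnames(mat) <- paste0("s", 1:12)
  res <- diff_expression(mat, rep(c("A", "B"), each = 6),
                         mode = "intensity")
  expect_false(res$significant[res$gene == "exact"])
  expect_true(res$significant[res$gene == "above"])
})

test_that("methylation calls need both FDR < 0.05 and |delta beta| > 0.2", {
  set.seed(43)
  n <- 20
  groups <- rep(c("A", "B"), each = 10)
  small <- c(rnorm(10, 0.40, 0.01), rnorm(10, 0.59, 0.01))  # delta ~ .19
  big <- c(rnorm(10, 0.20, 0.01), rnorm(10, 0.70, 0.01))    # delta ~ .5
  bm <- rbind(small = pmin(pmax(small, 0), 1),
              big = pmin(pmax(big, 0), 1),
              allna = rep(NA_real_, n),
              sparse = c(0.5, 0.6, rep(NA, 8), rnorm(10, 0.5, 0.05)))
  colnames(bm) <- paste0("s", 1:n)
  res <- diff_methylation(bm, groups)
  expect_false("allna" %in% res$probe)
  expect_false("sparse" %in% res$probe)
  expect_false(res$significant[res$probe == "small"])
  expect_true(res$significant[res$probe == "big"])
})

test_that("starburst coordinates, boundary rule and antisymmetry", {
  meth <- data.frame(probe = c("p1", "p2"), gene = c("g1", "g2"),
                     delta_beta = c(-0.3, 0.1), p = c(0.05, 1),
                     fdr = c(0.1, 1), significant = c(FALSE, FALSE))
  expr <- data.frame(gene = c("g1", "g2"), log2fc = c(1.2, 0.5),
                     p = c(0.05, 1), fdr = c(0.1, 1),
                     significant = c(FALSE, FALSE))
  sb <- starburst(meth, expr)
  expect_equal(sb$x[sb$gene == "g1"], -abs(log10(0.05)), tolerance = 1e-9)
  expect_equal(sb$y[sb$gene == "g1"], abs(log10(0.05)), tolerance = 1e-9)
  # p exactly 0.05 on both axes: boundary is NOT significant (strict <)
  expect_identical(sb$quadrant[sb$gene == "g1"], "ns")
  expect_equal(sb$x[sb$gene == "g2"], 0)
  expect_equal(sb$y[sb$gene == "g2"], 0)

  meth2 <- meth; meth2$delta_beta <- -meth2$delta_beta
  expr2 <- expr; expr2$log2fc <- -expr2$log2fc
  sb2 <- starburst(meth2, expr2)
  expect_equal(sb2$x, -sb$x); expect_equal(sb2$y, -sb$y)

  meth3 <- meth; meth3$p[1] <- 0.01
  expr3 <- expr; expr3$p[1] <- 0.001
  sb3 <- starburst(meth3, expr3)
  expect_identical(sb3$quadrant[sb3$gene == "g1"], "hypo_up")
  expect_identical(attr(sb3, "hypo_up"), "g1")
})

test_that("best (smallest-p) promoter probe represents each gene", {
  meth <- data.frame(probe = c("p1", "p2"), gene = c("g1", "g1"),
                     delta_beta = c(0.3, -0.4), p = c(0.2, 0.001))
  expr <- data.frame(gene = "g1", log2fc = 1, p = 0.001)
  sb <- starburst(meth, expr)
  expect_equal(nrow(sb), 1L)
  expect_lt(sb$x, 0)  # the smaller-p probe (hypo) wins
})

test_that("FET GO analysis keeps maximal overlaps and drops disjoint terms", {
  universe <- paste0("g", 1:50)
  terms <- list(hit = paste0("g", 1:10), miss = paste0("g", 41:50))
  res <- go_fet(paste0("g", 1:10), universe, terms)
  expect_true(res$significant[res$term == "hit"])
  expect_false(res$significant[res$term == "miss"])
  expect_equal(res$n_overlap[res$term == "miss"], 0L)
  # hypergeometric cross-check of the disjoint term's two-sided p
  ft <- fisher.test(matrix(c(0, 10, 10, 30), 2, 2, byrow = TRUE))
  expect_equal(res$p[res$term == "miss"], ft$p.value, tolerance = 1e-10)
  expect_equal(nrow(go_fet(character(0), universe, terms)), 0L)
})

test_that("alteration landscape excludes recurrent other-group genes and selects a minimal prefix", {
  # 6 samples in group A, 4 in B
  samples <- c(paste0("a", 1:6), paste0("b", 1:4))
  groups <- c(rep("A", 6), rep("B", 4))
  mat <- matrix(0L, 6, 10, dimnames = list(paste0("g", 1:6), samples))
  mat["g1", c("a1", "a2", "a3")] <- 1L          # strong, covers a1-a3
  mat["g2", c("a4", "a5")] <- 1L                # covers a4, a5
  mat["g3", c("a6")] <- 1L                      # covers a6
  mat["g4", c("a1", "b1", "b2")] <- 1L          # 2 alterations in B: excluded
  mat["g5", c("a2", "b1")] <- 1L                # 1 in B: allowed
  res <- suppressWarnings(alteration_landscape(mat, groups))
  tabA <- res$A$table
  expect_false("g4" %in% tabA$gene)
  expect_true("g5" %in% tabA$gene)
  sel <- res$A$selected
  # every A sample covered by the selected prefix
  expect_true(all(colSums(mat[sel, paste0("a", 1:6), drop = FALSE]) >= 1))
  # minimality: no shorter prefix of the p-ordering covers all A samples
  ord <- tabA$gene
  if (length(sel) > 1) {
    for (len in seq_len(length(sel) - 1)) {
      expect_false(all(colSums(mat[ord[seq_len(len)], paste0("a", 1:6),
                                   drop = FALSE]) >= 1))
    }
  }
  # a single gene altered in every A sample and nowhere else is the prefix
  mat2 <- matrix(0L, 2, 10, dimnames = list(c("h1", "h2"), samples))
  mat2["h1", paste0("a", 1:6)] <- 1L
  mat2["h2", "a1"] <- 1L
  res2 <- suppressWarnings(alteration_landscape(mat2, groups))
  expect_identical(res2$A$selected, "h1")
  # a sample with no alterations anywhere is reported uncovered
  mat3 <- mat2; mat3[, "a6"] <- 0L; mat3["h1", "a6"] <- 0L
  w <- capture_warnings(res3 <- alteration_landscape(mat3, groups))
  expect_true(any(grepl("uncovered", w)))
  expect_identical(res3$A$uncovered, "a6")
})
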
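# Differential expression and methylation with the headline thresholds,
# starburst integration of the two axes, Fisher-exact GO analysis of the
# integrated gene lists, and the alteration-landscape gene selection.

#' Differential expression between two groups
#'
#' `mode = "count"` analyses raw counts with the edgeR protocol (TMM
#' normalisation, common/tagwise dispersion, exact test); an internal
#' lognormal engine (`engine = "lognormal"`: Welch t on log2(count+1) with
#' a mean log-ratio effect) is available where the negative-binomial
#' machinery is not wanted. `mode = "intensity"` uses a two-sided
#' Mann-Whitney test per gene on array-style intensities. Both modes apply
#' Benjamini-Hochberg FDR; a gene is significant iff its fold change
#' strictly exceeds 1.5 in either direction and FDR < 0.05.
#'
#' @param matrix Gene x sample matrix (counts or intensities, linear
#'   scale).
#' @param groups Two-level labels over columns (>= 3 samples per group).
#' @param mode `"count"` or `"intensity"`.
#' @param engine Count-mode engine: `"edger"` (default) or `"lognormal"`.
#' @param fc_threshold Linear fold-change threshold (default 1.5, strict).
#' @param fdr_threshold FDR threshold (default 0.05).
#' @return Data frame (gene, log2fc, p, fdr, significant). Zero-variance
#'   genes get p = 1.
#' @export
diff_expression <- function(matrix, groups, mode = c("count", "intensity"),
                            engine = c("edger", "lognormal"),
                            fc_threshold = 1.5, fdr_threshold = 0.05) {
  mode <- match.arg(mode); engine <- match.arg(engine)
  f <- factor(groups)
  if (nlevels(f) != 2L) stopf("need exactly two groups")
  if (min(table(f)) < 3L) stopf("need >= 3 samples per group")
  i1 <- which(f == levels(f)[1]); i2 <- which(f == levels(f)[2])
  constant <- apply(matrix, 1L, function(r) length(unique(r)) == 1L)
  if (mode == "count" && engine == "edger") {
    dge <- edgeR::DGEList(counts = matrix, group = f)
    dge <- edgeR::calcNormFactors(dge)
    dge <- suppressMessages(edgeR::estimateDisp(dge))
    et <- edgeR::exactTest(dge, pair = levels(f))
    res <- et$table
    out <- data.frame(gene = rownames(matrix), log2fc = res$logFC,
                      p = res$PValue, stringsAsFactors = FALSE)
  } else if (mode == "count") {
    lm1 <- log2(matrix[, i1, drop = FALSE] + 1)
    lm2 <- log2(matrix[, i2, drop = FALSE] + 1)
    p <- vapply(seq_len(nrow(matrix)), function(g) {
      if (constant[g]) return(1)
      stats::t.test(lm2[g, ], lm1[g, ])$p.value
    }, numeric(1))
    out <- data.frame(gene = rownames(matrix),
                      log2fc = rowMeans(lm2) - rowMeans(lm1),
                      p = p, stringsAsFactors = FALSE)
  } else {
    p <- vapply(seq_len(nrow(matrix)), function(g) {
      if (constant[g]) return(1)
      suppressWarnings(stats::wilcox.test(matrix[g, i2], matrix[g, i1],
                                          alternative = "two.sided")$p.value)
    }, numeric(1))
    m1 <- rowMeans(matrix[, i1, drop = FALSE])
    m2 <- rowMeans(matrix[, i2, drop = FALSE])
    out <- data.frame(gene = rownames(matrix),
                      log2fc = log2(pmax(m2, .Machine$double.eps) /
                                      pmax(m1, .Machine$double.eps)),
                      p = p, stringsAsFactors = FALSE)
  }
  out$p[constant] <- 1
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out$significant <- abs(out$log2fc) > log2(fc_threshold) &
    out$fdr < fdr_threshold
  out
}

#' Differential methylation between two groups
#'
#' Per-probe two-sided Wilcoxon test on beta values with Benjamini-Hochberg
#' FDR; a probe is differentially methylated iff FDR < 0.05 and the
#' absolute difference of group mean betas (ignoring NA) strictly exceeds
#' 0.2. Probes with fewer than 3 non-NA values in either group are
#' skipped.
#'
#' @param beta_matrix Probe x sample matrix of betas in \[0, 1\] (NA
#'   allowed).
#' @param groups Two-level labels over columns.
#' @param fdr_threshold FDR threshold (default 0.05).
#' @param delta_threshold |delta beta| threshold (default 0.2, strict).
#' @return Data frame (probe, delta_beta, p, fdr, significant) over tested
#'   probes.
#' @export
diff_methylation <- function(beta_matrix, groups, fdr_threshold = 0.05,
                             delta_threshold = 0.2) {
  f <- factor(groups)
  if (nlevels(f) != 2L) stopf("need exactly two groups")
  rng <- range(beta_matrix, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1) stopf("beta values must lie in [0, 1]")
  i1 <- which(f == levels(f)[1]); i2 <- which(f == levels(f)[2])
  ok <- apply(beta_matrix, 1L, function(r)
    sum(!is.na(r[i1])) >= 3L && sum(!is.na(r[i2])) >= 3L)
  bm <- beta_matrix[ok, , drop = FALSE]
  if (nrow(bm) == 0L)
    return(data.frame(probe = character(0), delta_beta = numeric(0),
                      p = numeric(0), fdr = numeric(0),
                      significant = logical(0)))
  p <- vapply(seq_len(nrow(bm)), function(g) {
    x <- bm[g, i2]; y <- bm[g, i1]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(unique(c(x, y))) == 1L) return(1)
    suppressWarnings(stats::wilcox.test(x, y)$p.value)
  }, numeric(1))
  delta <- rowMeans(bm[, i2, drop = FALSE], na.rm = TRUE) -
    rowMeans(bm[, i1, drop = FALSE], na.rm = TRUE)
  out <- data.frame(probe = rownames(bm), delta_beta = unname(delta),
                    p = p, stringsAsFactors = FALSE)
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$fdr < fdr_threshold &
    abs(out$delta_beta) > delta_threshold
  out
}

#' Starburst integration of methylation and expression
#'
#' Joins gene-level methylation (best promoter probe = smallest p) with
#' differential expression and places each gene at
#' x = sign(delta beta) |log10 p_meth|, y = sign(log2fc) |log10 p_expr|.
#' Genes significant on both axes (p < 0.05, strict) fall in the
#' hypo-methylated/up-regulated or hyper-methylated/down-regulated lists.
#'
#' @param meth_results Data frame from [diff_methylation()] plus a `gene`
#'   column mapping probes to genes.
#' @param expr_results Data frame from [diff_expression()].
#' @param p_threshold Per-axis significance threshold (default 0.05).
#' @return Data frame (gene, x, y, quadrant) with attributes
#'   `hypo_up` and `hyper_down` (gene vectors).
#' @export
starburst <- function(meth_results, expr_results, p_threshold = 0.05) {
  if (is.null(meth_results$gene))
    stopf("meth_results must carry a 'gene' column (probe -> gene map)")
  # best probe per gene by smallest p
  mr <- meth_results[order(meth_results$p), , drop = FALSE]
  mr <- mr[!duplicated(mr$gene), , drop = FALSE]
  common <- intersect(mr$gene, expr_results$gene)
  mr <- mr[match(common, mr$gene), , drop = FALSE]
  er <- expr_results[match(common, expr_results$gene), , drop = FALSE]
  x <- sign(mr$delta_beta) * abs(log10(mr$p))
  y <- sign(er$log2fc) * abs(log10(er$p))
  sig <- mr$p < p_threshold & er$p < p_threshold
  quadrant <- rep("ns", length(common))
  quadrant[sig & mr$delta_beta < 0 & er$log2fc > 0] <- "hypo_up"
  quadrant[sig & mr$delta_beta > 0 & er$log2fc < 0] <- "hyper_down"
  quadrant[sig & mr$delta_beta > 0 & er$log2fc > 0] <- "hyper_up"
  quadrant[sig & mr$delta_beta < 0 & er$log2fc < 0] <- "hypo_down"
  out <- data.frame(gene = common, x = x, y = y, quadrant = quadrant,
                    stringsAsFactors = FALSE)
  attr(out, "hypo_up") <- out$gene[out$quadrant == "hypo_up"]
  attr(out, "hyper_down") <- out$gene[out$quadrant == "hyper_down"]
  out
}

#' Fisher-exact GO enrichment of a gene list
#'
#' Two-sided Fisher exact test per term on the 2x2 table (in list x in
#' term) over the gene universe, with Benjamini-Hochberg q-values; terms
#' pass at p < 0.05 and q < 0.25.
#'
#' @param gene_list Character vector (subset of `universe`).
#' @param universe Character vector of all considered genes.
#' @param term_sets Named list of gene sets.
#' @param p_threshold,q_threshold Selection thresholds (defaults 0.05 and
#'   0.25, strict).
#' @return Data frame (term, n_term, n_overlap, odds_ratio, p, q,
#'   significant); empty input gives an empty result.
#' @export
go_fet <- function(gene_list, universe, term_sets, p_threshold = 0.05,
                   q_threshold = 0.25) {
  empty <- data.frame(term = character(0), n_term = integer(0),
                      n_overlap = integer(0), odds_ratio = numeric(0),
                      p = numeric(0), q = numeric(0),
                      significant = logical(0), stringsAsFactors = FALSE)
  if (length(gene_list) == 0L) return(empty)
  if (!all(gene_list %in% universe)) stopf("gene_list must be within universe")
  rows <- lapply(names(term_sets), function(tn) {
    term <- intersect(term_sets[[tn]], universe)
    if (length(term) == 0L) return(NULL)
    a <- length(intersect(gene_list, term))
    b <- length(gene_list) - a
    c_ <- length(term) - a
    d <- length(universe) - a - b - c_
    ft <- stats::fisher.test(matrix(c(a, b, c_, d), 2, 2, byrow = TRUE),
                             alternative = "two.sided")
    data.frame(term = tn, n_term = length(term), n_overlap = a,
               odds_ratio = unname(ft$estimate), p = ft$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$p < p_threshold & out$q < q_threshold
  out[order(out$p), , drop = FALSE]
}

# One-sided (greater) comparison of alteration frequency in group G versus
# the other group; normal-approximation two-sample proportion test with an
# exact (one-sided Fisher) fallback when any expected count is small.
proportion_test_greater <- function(x1, n1, x2, n2,
                                    method = c("auto", "normal", "exact")) {
  method <- match.arg(method)
  small <- any(c(x1, n1 - x1, x2, n2 - x2) < 5)
  if (method == "exact" || (method == "auto" && small)) {
    tab <- matrix(c(x1, n1 - x1, x2, n2 - x2), 2, 2, byrow = TRUE)
    return(stats::fisher.test(tab, alternative = "greater")$p.value)
  }
  suppressWarnings(stats::prop.test(c(x1, x2), c(n1, n2),
                                    alternative = "greater",
                                    correct = FALSE)$p.value)
}

#' Alteration-landscape gene selection
#'
#' For the direction "enriched in group G": genes with more than one
#' altered sample in the other group are removed; remaining genes are
#' tested with a one-sided ("greater") proportion test of alteration
#' frequency in G versus the rest, ordered by increasing p, and the
#' shortest prefix of that ordering covering every G sample with at least
#' one alteration is selected. Both group directions are emitted.
#'
#' @param alteration_matrix Binary gene x patient matrix (1 = non-
#'   synonymous mutation or CNV present).
#' @param groups Two-level labels over patients.
#' @param method Proportion-test flavour passed to the per-gene test
#'   (`"auto"`, `"normal"`, `"exact"`).
#' @return Named list (one per group level) of lists with `table` (gene,
#'   freq_in, freq_out, p, selected), `selected` (gene vector in selection
#'   order), and `uncovered` (G samples no candidate gene could cover).
#' @export
alteration_landscape <- function(alteration_matrix, groups,
                                 method = c("auto", "normal", "exact")) {
  method <- match.arg(method)
  if (!all(alteration_matrix %in% c(0, 1))) stopf("matrix must be binary")
  f <- factor(groups)
  if (nlevels(f) != 2L) stopf("need exactly two groups")
  out <- list()
  for (g in levels(f)) {
    gi <- which(f == g); oi <- which(f != g)
    other_alt <- rowSums(alteration_matrix[, oi, drop = FALSE])
    keep <- other_alt <= 1
    genes <- rownames(alteration_matrix)[keep]
    if (length(genes) == 0L) {
      out[[g]] <- list(table = NULL, selected = character(0),
                       uncovered = colnames(alteration_matrix)[gi])
      next
    }
    sub <- alteration_matrix[keep, , drop = FALSE]
    x1 <- rowSums(sub[, gi, drop = FALSE]); n1 <- length(gi)
    x2 <- rowSums(sub[, oi, drop = FALSE]); n2 <- length(oi)
    p <- vapply(seq_along(genes), function(i)
      proportion_test_greater(x1[i], n1, x2[i], n2, method), numeric(1))
    ord <- order(p, -x1)
    tab <- data.frame(gene = genes[ord],
                      freq_in = 100 * x1[ord] / n1,
                      freq_out = 100 * x2[ord] / n2,
                      p = p[ord], selected = FALSE,
                      row.names = NULL, stringsAsFactors = FALSE)
    covered <- rep(FALSE, length(gi))
    prefix_len <- 0L
    for (i in seq_len(nrow(tab))) {
      hit <- sub[match(tab$gene[i], rownames(sub)), gi] == 1
      covered <- covered | hit
      prefix_len <- i
      if (all(covered)) break
    }
    if (!all(covered)) {
      warnf("group %s: %d sample(s) uncovered by any candidate gene",
            g, sum(!covered))
    }
    tab$selected <- seq_len(nrow(tab)) <= prefix_len & all(covered)
    out[[g]] <- list(table = tab,
                     selected = if (all(covered)) tab$gene[seq_len(prefix_len)]
                                else character(0),
                     uncovered = colnames(alteration_matrix)[gi][!covered])
  }
  out
}
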
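# MWW-GST enrichment: per-sample Normalized Enrichment Score for immune
# cell signatures, easy-ensemble MWW ranked differential statistics, GO
# style enrichment on the ranked output, and overlap-coefficient edges for
# enrichment-map networks.

#' MWW-GST Normalized Enrichment Score
#'
#' NES = 1 - U/(m n) with U = n m + m(m+1)/2 - T, where T is the sum of the
#' (mid-tie) ranks of the m in-set genes among all m + n genes. NES
#' estimates the probability that an in-set gene's value exceeds an
#' out-of-set gene's value.
#'
#' @param values Named numeric vector (e.g. one sample's expression over
#'   all genes).
#' @param gene_set Character vector of gene symbols.
#' @param name Optional label stored on the result.
#' @return List of class `nes_result` with `name`, `m`, `n`, `T`, `U`,
#'   `nes`, `p` (normal-approximation one-sided p for enrichment), or
#'   `NULL` if no set gene is present.
#' @export
nes <- function(values, gene_set, name = NA_character_) {
  inset <- names(values) %in% gene_set
  m <- sum(inset); n <- sum(!inset)
  if (m == 0L) {
    warnf("no gene of the set present in the ranking; set skipped")
    return(NULL)
  }
  if (n == 0L) stopf("gene set covers the whole ranking; NES undefined")
  rk <- rank(values, ties.method = "average")
  T_ <- sum(rk[inset])
  U <- n * m + m * (m + 1) / 2 - T_
  nes_val <- 1 - U / (m * n)
  # normal approximation with tie correction, one-sided for enrichment
  N <- m + n
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- m * n / 12 * ((N + 1) - tie_term)
  z <- (m * n / 2 - U) / sqrt(max(sigma2, .Machine$double.eps))
  structure(list(name = name, m = m, n = n, T = T_, U = U, nes = nes_val,
                 p = stats::pnorm(z, lower.tail = FALSE)),
            class = "nes_result")
}

#' @export
print.nes_result <- function(x, ...) {
  cat(sprintf("NES %s: %.4f (m = %d, n = %d, U = %.1f, p = %.3g)\n",
              if (is.na(x$name)) "" else x$name, x$nes, x$m, x$n, x$U, x$p))
  invisible(x)
}

#' Per-sample NES matrix for a collection of signatures
#'
#' Ranks genes within each sample and computes one NES per (signature,
#' sample).
#'
#' @param expression Gene x sample numeric matrix with gene rownames.
#' @param signatures Named list of gene-symbol vectors.
#' @return Signature x sample matrix of NES values.
#' @export
nes_matrix <- function(expression, signatures) {
  out <- matrix(NA_real_, length(signatures), ncol(expression),
                dimnames = list(names(signatures), colnames(expression)))
  for (j in seq_len(ncol(expression))) {
    v <- stats::setNames(expression[, j], rownames(expression))
    for (s in names(signatures)) {
      r <- nes(v, signatures[[s]], name = s)
      if (!is.null(r)) out[s, j] <- r$nes
    }
  }
  out
}

#' Median-split stratification of per-sample NES
#'
#' Labels a sample `"high"` iff its NES strictly exceeds the cohort median;
#' ties at the median go to `"low"`.
#'
#' @param nes_values Per-sample NES for one signature (>= 2 samples).
#' @return Character vector of `"high"`/`"low"` labels.
#' @export
enrichment_stratify <- function(nes_values) {
  if (length(nes_values) < 2L) stopf("need at least 2 samples to stratify")
  if (length(unique(nes_values)) == 1L) {
    warnf("all NES equal; every sample labelled 'low'")
    return(rep("low", length(nes_values)))
  }
  ifelse(nes_values > stats::median(nes_values), "high", "low")
}

# Per-gene MWW U statistic of group1 against group2 over the rows of a
# matrix (mid-tie ranks); U is counted for group1.
mww_u_genewise <- function(mat, idx1, idx2) {
  n1 <- length(idx1); n2 <- length(idx2)
  sub <- mat[, c(idx1, idx2), drop = FALSE]
  rk <- t(apply(sub, 1L, rank, ties.method = "average"))
  rowSums(rk[, seq_len(n1), drop = FALSE]) - n1 * (n1 + 1) / 2
}

#' Easy-ensemble MWW differential statistic
#'
#' For unbalanced two-group comparisons: the majority class is subsampled
#' to the minority size, per-gene MWW U statistics (for the first group)
#' are computed between the balanced classes, the procedure is repeated K
#' times and the statistics averaged. Balanced inputs need no subsampling
#' and force K = 1.
#'
#' @param expression Gene x sample matrix.
#' @param group_labels Two-level labels over the columns; the first level
#'   (alphabetically, or of the factor) is the class whose U is reported.
#' @param K Number of subsampling repetitions (default 10000).
#' @param seed Integer seed.
#' @return Data frame (gene, u_bar, nes_gene) sorted by decreasing `u_bar`;
#'   `nes_gene` is u_bar normalised by the balanced m*n (a probability).
#' @export
ee_mww <- function(expression, group_labels, K = 10000L, seed = 1L) {
  f <- factor(group_labels)
  if (nlevels(f) != 2L) stopf("ee_mww needs exactly two groups")
  i1 <- which(f == levels(f)[1]); i2 <- which(f == levels(f)[2])
  if (length(i1) == length(i2)) {
    K <- 1L
    u <- mww_u_genewise(expression, i1, i2)
    s <- length(i1)
  } else {
    set.seed(seed)
    minority_first <- length(i1) < length(i2)
    s <- min(length(i1), length(i2))
    acc <- numeric(nrow(expression))
    for (k in seq_len(K)) {
      if (minority_first) {
        acc <- acc + mww_u_genewise(expression, i1, sample(i2, s))
      } else {
        acc <- acc + mww_u_genewise(expression, sample(i1, s), i2)
      }
    }
    u <- acc / K
  }
  out <- data.frame(gene = rownames(expression), u_bar = unname(u),
                    nes_gene = unname(u) / (s * s), stringsAsFactors = FALSE)
  out[order(-out$u_bar), , drop = FALSE]
}

#' GO-style enrichment on a ranked gene statistic
#'
#' Computes the MWW-GST NES of each term's genes on the ranked statistic
#' (e.g. the averaged U from [ee_mww()]), derives q-values by
#' Benjamini-Hochberg on the one-sided MWW-GST p-values, and keeps terms
#' passing both thresholds.
#'
#' @param ranked_stats Named numeric vector (gene -> statistic).
#' @param term_sets Named list of gene sets (GMT-like).
#' @param nes_threshold Keep terms with NES strictly above this (default
#'   0.6).
#' @param q_threshold Keep terms with q strictly below this (default 1e-5).
#' @return Data frame (term, m, nes, p, q, significant), `NULL`-skipping
#'   terms with no gene in the ranking.
#' @export
go_enrichment <- function(ranked_stats, term_sets, nes_threshold = 0.6,
                          q_threshold = 1e-5) {
  rows <- lapply(names(term_sets), function(tn) {
    r <- suppressWarnings(nes(ranked_stats, term_sets[[tn]], name = tn))
    if (is.null(r)) return(NULL)
    data.frame(term = tn, m = r$m, nes = r$nes, p = r$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0L) return(out)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$nes > nes_threshold & out$q < q_threshold
  out[order(out$q, -out$nes), , drop = FALSE]
}

#' Overlap-coefficient edges for an enrichment map
#'
#' OC = |A intersect B| / min(|A|, |B|); edges with OC strictly above the
#' cutoff are kept. Node size (set size) is attached for rendering.
#'
#' @param term_sets Named list of gene sets (the significant terms).
#' @param oc_cutoff Overlap-coefficient cutoff (default 0.5).
#' @return List with `edges` (data frame source, target, oc) and `nodes`
#'   (data frame term, size).
#' @export
enrichment_map_edges <- function(term_sets, oc_cutoff = 0.5) {
  nms <- names(term_sets)
  edges <- list()
  if (length(nms) >= 2L) for (i in seq_len(length(nms) - 1L)) {
    for (j in (i + 1L):length(nms)) {
      A <- term_sets[[i]]; B <- term_sets[[j]]
      oc <- length(intersect(A, B)) / min(length(A), length(B))
      if (oc > oc_cutoff) {
        edges[[length(edges) + 1L]] <-
          data.frame(source = nms[i], target = nms[j], oc = oc,
                     stringsAsFactors = FALSE)
      }
    }
  }
  list(edges = if (length(edges)) do.call(rbind, edges) else
         data.frame(source = character(0), target = character(0),
                    oc = numeric(0), stringsAsFactors = FALSE),
       nodes = data.frame(term = nms,
                          size = vapply(term_sets, length, integer(1)),
                          row.names = NULL, stringsAsFactors = FALSE))
}
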
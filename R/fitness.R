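# The neoantigen fitness (quality) model: gapless local alignment of mutant
# 9-mers against an epitope database, sigmoid TCR recognition probability R,
# binding amplitude A, and their product NRP.

.nq_env <- new.env(parent = emptyenv())

#' BLOSUM62 substitution matrix restricted to the 20 standard amino acids
#'
#' Fetched once from \pkg{Biostrings} and cached; row/column order follows
#' the standard alphabet.
#'
#' @return A 20 x 20 integer matrix with amino-acid dimnames.
#' @export
blosum62 <- function() {
  if (is.null(.nq_env$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .nq_env$blosum62 <- e$BLOSUM62[AA_ALPHABET, AA_ALPHABET]
  }
  .nq_env$blosum62
}

#' Fitness model parameters
#'
#' Container for the tunable quantities of the quality model. `a` is the
#' horizontal displacement of the recognition sigmoid (in alignment-score
#' units), `k` its steepness at `a`. `eps_over_L` is the pseudo-count over
#' peptide concentration entering the amplitude; the default is 3e-4.
#' `aggregation` selects how epitope alignment scores are combined into R:
#' `"max-logistic"` applies the sigmoid to the best score, `"partition-sum"`
#' uses the multi-epitope partition form Z/(1+Z) with
#' Z = sum_e exp(k (s_e - a)). With a single epitope the two coincide.
#'
#' @param a Horizontal displacement of the sigmoid.
#' @param k Steepness (> 0).
#' @param eps_over_L Pseudo-count ratio (>= 0).
#' @param matrix Substitution matrix (defaults to BLOSUM62).
#' @param aggregation `"max-logistic"` or `"partition-sum"`.
#' @return An object of class `nq_params`.
#' @export
nq_params <- function(a = 21, k = 1.6, eps_over_L = 3e-4,
                      matrix = blosum62(),
                      aggregation = c("max-logistic", "partition-sum")) {
  aggregation <- match.arg(aggregation)
  if (!is.numeric(k) || k <= 0) stopf("k must be > 0 (got %s)", format(k))
  if (!is.numeric(eps_over_L) || eps_over_L < 0) stopf("eps_over_L must be >= 0")
  structure(list(a = a, k = k, eps_over_L = eps_over_L,
                 matrix = matrix, aggregation = aggregation),
            class = "nq_params")
}

#' @export
print.nq_params <- function(x, ...) {
  cat(sprintf("Fitness parameters: a = %g, k = %g, eps/[L] = %g, %s aggregation\n",
              x$a, x$k, x$eps_over_L, x$aggregation))
  invisible(x)
}

# Encode peptides as an integer matrix (rows = peptides, cols = positions).
# All sequences must share the same length.
encode_peptides <- function(peptides) {
  n <- nchar(peptides)
  if (length(unique(n)) > 1L) stopf("peptides must have equal length")
  m <- matrix(match(unlist(strsplit(peptides, "")), AA_ALPHABET),
              nrow = length(peptides), byrow = TRUE)
  if (anyNA(m)) stopf("non-standard residue in peptide set")
  m
}

# All w-length windows of each epitope, encoded; returns NULL if none.
epitope_windows <- function(epitopes, w = 9L) {
  keep <- nchar(epitopes) >= w
  if (!any(keep)) return(NULL)
  pieces <- lapply(which(keep), function(i) {
    s <- epitopes[i]
    L <- nchar(s)
    starts <- seq_len(L - w + 1L)
    data.frame(epitope = i, window = substring(s, starts, starts + w - 1L),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, pieces)
}

#' Gapless local alignment score of a peptide against one epitope
#'
#' The score is the maximum, over all placements of the full peptide within
#' the epitope, of the summed substitution-matrix values (no gaps). Epitopes
#' shorter than the peptide are not comparable and yield `NA`.
#'
#' @param peptide Amino-acid string (typically a 9-mer).
#' @param epitope Amino-acid string.
#' @param matrix Substitution matrix; default BLOSUM62.
#' @return Integer score, or `NA` if the epitope is shorter than the peptide.
#' @export
align_score <- function(peptide, epitope, matrix = blosum62()) {
  w <- nchar(peptide)
  if (nchar(epitope) < w) return(NA_integer_)
  p <- aa_chars(peptide)
  e <- aa_chars(epitope)
  if (!all(p %in% rownames(matrix)) || !all(e %in% rownames(matrix)))
    stopf("sequence contains residues absent from the substitution matrix")
  starts <- seq_len(length(e) - w + 1L)
  max(vapply(starts, function(s) {
    sum(matrix[cbind(p, e[s:(s + w - 1L)])])
  }, numeric(1)))
}

# Vectorised peptide x epitope score matrix: rows = peptides, cols =
# epitopes; entry = best gapless window score; NA column if epitope < w.
align_score_matrix <- function(peptides, epitopes, matrix = blosum62()) {
  w <- unique(nchar(peptides))
  if (length(w) != 1L) stopf("peptides must share one length")
  out <- matrix(NA_real_, length(peptides), length(epitopes))
  wins <- epitope_windows(epitopes, w)
  if (is.null(wins)) return(out)
  P <- encode_peptides(peptides)
  W <- encode_peptides(wins$window)
  S <- matrix(0, nrow(P), nrow(W))
  for (j in seq_len(w)) {
    S <- S + matrix(matrix[cbind(rep(P[, j], times = nrow(W)),
                                 rep(W[, j], each = nrow(P)))],
                    nrow(P), nrow(W))
  }
  for (ei in unique(wins$epitope)) {
    cols <- which(wins$epitope == ei)
    out[, ei] <- if (length(cols) == 1L) S[, cols] else
      do.call(pmax, as.data.frame(S[, cols, drop = FALSE]))
  }
  out
}

#' TCR recognition probability R
#'
#' Applies the sigmoid recognition model to the alignment scores of a mutant
#' peptide against an epitope database. Under `"max-logistic"` aggregation,
#' R = 1 / (1 + exp(-k (s* - a))) with s* the best alignment score; under
#' `"partition-sum"`, R = Z / (1 + Z) with Z = sum_e exp(k (s_e - a)).
#'
#' @param peptide Mutant peptide (string), or a numeric vector of
#'   precomputed alignment scores via `scores`.
#' @param epitopes Character vector of epitope sequences.
#' @param params An [nq_params()] object.
#' @param scores Optional numeric vector of alignment scores (one per
#'   epitope); when supplied, `peptide`/`epitopes` are not aligned again.
#' @return R in \[0, 1\], or `NA` if no epitope was comparable.
#' @export
recognition <- function(peptide = NULL, epitopes = NULL, params = nq_params(),
                        scores = NULL) {
  if (is.null(scores)) {
    scores <- vapply(epitopes, function(e)
      as.numeric(align_score(peptide, e, params$matrix)), numeric(1))
  }
  scores <- scores[!is.na(scores)]
  if (length(scores) == 0L) {
    warnf("no comparable epitope; recognition undefined")
    return(NA_real_)
  }
  if (params$aggregation == "max-logistic") {
    plogis(params$k * (max(scores) - params$a))
  } else {
    # log-sum-exp for numerical stability
    lz <- params$k * (scores - params$a)
    m <- max(lz)
    logz <- m + log(sum(exp(lz - m)))
    plogis(logz)
  }
}

#' Binding amplitude A
#'
#' Ratio of the relative probability that the mutant peptide is bound to MHC
#' class I to the relative probability that its wild-type counterpart is not:
#' A = (Kd_WT / Kd_MT) * 1 / (1 + eps_over_L * Kd_WT), the pseudo-count
#' approximation with dissociation constants in nM.
#'
#' @param kd_mt Mutant dissociation constant (IC50, nM), > 0.
#' @param kd_wt Wild-type dissociation constant on the same allele, > 0.
#' @param eps_over_L Pseudo-count over peptide concentration (default 3e-4).
#' @return Amplitude (vectorised over inputs).
#' @export
amplitude <- function(kd_mt, kd_wt, eps_over_L = 3e-4) {
  if (any(kd_mt <= 0) || any(kd_wt <= 0))
    stopf("dissociation constants must be positive")
  (kd_wt / kd_mt) / (1 + eps_over_L * kd_wt)
}

#' Score neoantigens with the fitness model
#'
#' Computes, for every neoantigen row, the best alignment score against the
#' epitope database, the recognition probability R, the amplitude A and
#' NRP = A x R.
#'
#' @param neoantigens Data frame from [call_neoantigens()] (columns
#'   `mt_peptide`, `kd_mt`, `kd_wt` at minimum).
#' @param epitopes Character vector of epitope sequences (an epitope
#'   database), or a data frame with a `sequence` column.
#' @param params An [nq_params()] object.
#' @return `neoantigens` with columns `align_best`, `R`, `A`, `nrp` added.
#'   Rows with no comparable epitope get `NA` R/nrp and a warning.
#' @export
score_neoantigens <- function(neoantigens, epitopes, params = nq_params()) {
  if (is.data.frame(epitopes)) epitopes <- epitopes$sequence
  if (length(epitopes) == 0L) stopf("epitope database is empty")
  if (nrow(neoantigens) == 0L) {
    neoantigens$align_best <- numeric(0)
    neoantigens$R <- numeric(0)
    neoantigens$A <- numeric(0)
    neoantigens$nrp <- numeric(0)
    return(neoantigens)
  }
  uniq <- unique(neoantigens$mt_peptide)
  S <- align_score_matrix(uniq, epitopes, params$matrix)
  idx <- match(neoantigens$mt_peptide, uniq)
  if (params$aggregation == "max-logistic") {
    best <- apply(S, 1L, function(r) if (all(is.na(r))) NA_real_ else max(r, na.rm = TRUE))
    R_u <- plogis(params$k * (best - params$a))
  } else {
    best <- rep(NA_real_, nrow(S))
    R_u <- rep(NA_real_, nrow(S))
    for (i in seq_len(nrow(S))) {
      r <- S[i, !is.na(S[i, ])]
      if (length(r) == 0L) next
      best[i] <- max(r)
      lz <- params$k * (r - params$a)
      m <- max(lz)
      R_u[i] <- plogis(m + log(sum(exp(lz - m))))
    }
  }
  if (anyNA(R_u)) warnf("%d peptide(s) had no comparable epitope; NRP undefined for them",
                        sum(is.na(R_u)))
  neoantigens$align_best <- best[idx]
  neoantigens$R <- R_u[idx]
  neoantigens$A <- amplitude(neoantigens$kd_mt, neoantigens$kd_wt, params$eps_over_L)
  neoantigens$nrp <- neoantigens$A * neoantigens$R
  neoantigens
}

#' Per-patient neoantigen quality
#'
#' The total neoantigen quality of a patient is the arithmetic mean of the
#' NRPs of all that patient's neoantigens. Patients with zero scoreable
#' neoantigens receive quality 0 (they cannot exceed a positive cohort mean
#' and fall in the low-quality group).
#'
#' @param scored Data frame from [score_neoantigens()] with `patient_id`
#'   and `nrp` columns.
#' @param patients Optional character vector of patient ids to report
#'   (patients absent from `scored` get quality 0).
#' @return Data frame (patient_id, n_neoantigens, quality).
#' @export
patient_quality <- function(scored, patients = NULL) {
  ok <- scored[!is.na(scored$nrp), , drop = FALSE]
  ids <- if (is.null(patients)) sort(unique(scored$patient_id)) else patients
  n <- vapply(ids, function(p) sum(ok$patient_id == p), integer(1))
  q <- vapply(ids, function(p) {
    v <- ok$nrp[ok$patient_id == p]
    if (length(v) == 0L) 0 else mean(v)
  }, numeric(1))
  data.frame(patient_id = ids, n_neoantigens = n, quality = q,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Compare neoantigen-epitope similarity between quality groups
#'
#' For each (assay type, qualitative label) stratum of a labelled epitope
#' set, computes each neoantigen's similarity as its best gapless alignment
#' score against the stratum's epitopes, then compares the high- and
#' low-quality groups with a two-sided Mann-Whitney U test.
#'
#' @param high_peptides,low_peptides Character vectors of mutant peptides in
#'   the high- and low-quality groups.
#' @param epitope_table Data frame with columns `sequence`, `assay_type`,
#'   `qualitative`.
#' @param matrix Substitution matrix.
#' @return Data frame (assay_type, qualitative, n_high, n_low, median_high,
#'   median_low, direction, p).
#' @export
iedb_similarity_comparison <- function(high_peptides, low_peptides,
                                       epitope_table, matrix = blosum62()) {
  strata <- unique(epitope_table[, c("assay_type", "qualitative")])
  res <- lapply(seq_len(nrow(strata)), function(i) {
    sel <- epitope_table$assay_type == strata$assay_type[i] &
      epitope_table$qualitative == strata$qualitative[i]
    eps <- epitope_table$sequence[sel]
    if (length(eps) == 0L) return(NULL)
    sim <- function(peps) {
      if (length(peps) == 0L) return(numeric(0))
      S <- align_score_matrix(peps, eps, matrix)
      apply(S, 1L, function(r) if (all(is.na(r))) NA_real_ else max(r, na.rm = TRUE))
    }
    hi <- sim(high_peptides); lo <- sim(low_peptides)
    hi <- hi[!is.na(hi)]; lo <- lo[!is.na(lo)]
    if (length(hi) == 0L || length(lo) == 0L) return(NULL)
    p <- stats::wilcox.test(hi, lo, alternative = "two.sided", exact = NULL)$p.value
    data.frame(assay_type = strata$assay_type[i],
               qualitative = strata$qualitative[i],
               n_high = length(hi), n_low = length(lo),
               median_high = stats::median(hi), median_low = stats::median(lo),
               direction = ifelse(stats::median(hi) >= stats::median(lo),
                                  "high>low", "low>high"),
               p = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
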
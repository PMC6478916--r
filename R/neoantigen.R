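# Enumeration of mutant/wild-type 9-mer pairs from missense mutations, the
# stringent binding-affinity neoantigen filter, the quantity model and DAI.

PEPTIDE_LEN <- 9L
IC50_THRESHOLD <- 500

#' Enumerate mutant/wild-type 9-mer pairs for one mutation
#'
#' Every 9-residue window of the protein context that contains the
#' substituted position and lies fully inside the context yields one pair;
#' windows truncated by the protein ends are dropped, so an interior residue
#' gives 9 pairs and a terminal one a single pair. `window_offset` is the
#' 0-based position of the mutant residue within the 9-mer.
#'
#' @param mutation One-row data frame (or list) with `patient_id`, `gene`,
#'   `protein_context`, `position` (1-based), `ref`, `alt`.
#' @return Data frame of pairs (patient_id, gene, window_offset, mt_peptide,
#'   wt_peptide); zero rows (with a warning) if the context is shorter
#'   than 9.
#' @export
enumerate_pairs <- function(mutation) {
  ctx <- mutation$protein_context
  pos <- as.integer(mutation$position)
  L <- nchar(ctx)
  empty <- data.frame(patient_id = character(0), gene = character(0),
                      window_offset = integer(0), mt_peptide = character(0),
                      wt_peptide = character(0), stringsAsFactors = FALSE)
  if (L < PEPTIDE_LEN) {
    warnf("context of length %d too short for a 9-mer; no pairs", L)
    return(empty)
  }
  if (substr(ctx, pos, pos) != mutation$ref)
    stopf("context has '%s' at position %d, not ref '%s'",
          substr(ctx, pos, pos), pos, mutation$ref)
  mt_ctx <- ctx
  substr(mt_ctx, pos, pos) <- mutation$alt
  starts <- max(1L, pos - PEPTIDE_LEN + 1L):min(L - PEPTIDE_LEN + 1L, pos)
  starts <- starts[starts >= 1L & starts + PEPTIDE_LEN - 1L <= L]
  if (length(starts) == 0L) return(empty)
  wt <- substring(ctx, starts, starts + PEPTIDE_LEN - 1L)
  mt <- substring(mt_ctx, starts, starts + PEPTIDE_LEN - 1L)
  keep <- is_aa_string(wt) & is_aa_string(mt)
  if (!all(keep)) warnf("dropped %d window(s) with non-standard residues", sum(!keep))
  data.frame(patient_id = mutation$patient_id, gene = mutation$gene,
             window_offset = pos - starts[keep],
             mt_peptide = mt[keep], wt_peptide = wt[keep],
             stringsAsFactors = FALSE)
}

#' Enumerate pairs for a mutation table
#'
#' @param mutations Data frame of validated mutation records.
#' @return Row-bound pairs from [enumerate_pairs()] applied per row.
#' @export
enumerate_pairs_all <- function(mutations) {
  L <- nchar(mutations$protein_context)
  pos <- as.integer(mutations$position)
  lo <- pmax(1L, pos - PEPTIDE_LEN + 1L)
  hi <- pmin(L - PEPTIDE_LEN + 1L, pos)
  nw <- pmax(0L, hi - lo + 1L)
  if (any(nw == 0L)) warnf("%d mutation(s) with context too short for a 9-mer",
                           sum(nw == 0L))
  row_i <- rep(seq_len(nrow(mutations)), nw)
  starts <- sequence(nw) + lo[row_i] - 1L
  ctx <- mutations$protein_context[row_i]
  mt_ctx <- mutations$protein_context
  bad_ref <- substr(mt_ctx, pos, pos) != mutations$ref
  if (any(bad_ref)) stopf("context/ref mismatch in %d row(s)", sum(bad_ref))
  substr(mt_ctx, pos, pos) <- mutations$alt
  wt <- substring(ctx, starts, starts + PEPTIDE_LEN - 1L)
  mt <- substring(mt_ctx[row_i], starts, starts + PEPTIDE_LEN - 1L)
  keep <- is_aa_string(wt) & is_aa_string(mt)
  if (!all(keep)) warnf("dropped %d window(s) with non-standard residues",
                        sum(!keep))
  data.frame(patient_id = mutations$patient_id[row_i][keep],
             gene = mutations$gene[row_i][keep],
             window_offset = (pos[row_i] - starts)[keep],
             mt_peptide = mt[keep], wt_peptide = wt[keep],
             stringsAsFactors = FALSE)
}

#' Apply the stringent neoantigen affinity filter
#'
#' A (pair, allele) combination is called a neoantigen iff the mutant
#' peptide's IC50 on that allele is strictly below 500 nM and the wild-type
#' peptide's IC50 exceeds 500 nM on every one of the patient's HLA class I
#' alleles. A pair may therefore yield several neoantigens (one per passing
#' allele). Combinations with any required affinity missing are skipped and
#' tallied, never defaulted.
#'
#' @param pairs Data frame from [enumerate_pairs_all()] (one patient's
#'   pairs).
#' @param affinities An `affinity_lookup`.
#' @param alleles The patient's HLA class I alleles (typically six
#'   four-digit names).
#' @param threshold_nM Binding threshold (default 500).
#' @return List with `neoantigens` (data frame: pair columns plus `allele`,
#'   `kd_mt`, `kd_wt`, `dai`) and `incomplete` (count of skipped
#'   combinations with missing affinities).
#' @export
call_neoantigens <- function(pairs, affinities, alleles,
                             threshold_nM = IC50_THRESHOLD) {
  alleles <- unique(alleles)
  nr <- nrow(pairs); na <- length(alleles)
  empty <- cbind(pairs[0, , drop = FALSE],
                 data.frame(allele = character(0), kd_mt = numeric(0),
                            kd_wt = numeric(0), dai = numeric(0),
                            stringsAsFactors = FALSE))
  if (nr == 0L) return(list(neoantigens = empty, incomplete = 0L))
  # bulk-query all (peptide, allele) combinations at once
  mt_kd <- matrix(affinity_query(affinities,
                                 rep(pairs$mt_peptide, each = na),
                                 rep(alleles, times = nr)), nr, na,
                  byrow = TRUE)
  wt_kd <- matrix(affinity_query(affinities,
                                 rep(pairs$wt_peptide, each = na),
                                 rep(alleles, times = nr)), nr, na,
                  byrow = TRUE)
  wt_complete <- rowSums(is.na(wt_kd)) == 0L
  wt_pass <- wt_complete & rowSums(wt_kd <= threshold_nM) == 0L
  incomplete <- as.integer(sum(is.na(mt_kd)) +
                             sum((!wt_complete) * rowSums(!is.na(mt_kd))))
  keep <- which(!is.na(mt_kd) & mt_kd < threshold_nM & wt_pass,
                arr.ind = TRUE)
  if (nrow(keep) == 0L) return(list(neoantigens = empty,
                                    incomplete = incomplete))
  keep <- keep[order(keep[, 1], keep[, 2]), , drop = FALSE]
  neo <- pairs[keep[, 1], , drop = FALSE]
  neo$allele <- alleles[keep[, 2]]
  neo$kd_mt <- mt_kd[keep]
  neo$kd_wt <- wt_kd[keep]
  neo$dai <- dai(neo$kd_mt, neo$kd_wt)
  rownames(neo) <- NULL
  list(neoantigens = neo, incomplete = incomplete)
}

#' Call neoantigens for a cohort
#'
#' @param pairs Pairs for the whole cohort (with `patient_id`).
#' @param affinities An `affinity_lookup`.
#' @param genotypes Named list of `hla_genotype` objects (patients without a
#'   complete three-locus consensus are skipped with a warning).
#' @param threshold_nM Binding threshold (default 500).
#' @return List with `neoantigens` (row-bound) and `incomplete` (total).
#' @export
call_neoantigens_cohort <- function(pairs, affinities, genotypes,
                                    threshold_nM = IC50_THRESHOLD) {
  # one bulk affinity query for the whole cohort, then the same filter as
  # call_neoantigens() applied per (pair, allele); equality with the
  # per-patient path is asserted in the test suite
  patients <- unique(pairs$patient_id)
  usable <- character(0)
  allele_sets <- list()
  for (p in patients) {
    g <- genotypes[[p]]
    if (is.null(g) || !g$complete) {
      warnf("patient %s skipped: no complete HLA consensus", p)
      next
    }
    usable <- c(usable, p)
    allele_sets[[p]] <- unique(g$alleles)
  }
  empty <- cbind(pairs[0, , drop = FALSE],
                 data.frame(allele = character(0), kd_mt = numeric(0),
                            kd_wt = numeric(0), dai = numeric(0),
                            stringsAsFactors = FALSE))
  keep_pair <- pairs$patient_id %in% usable
  if (!any(keep_pair))
    return(list(neoantigens = empty, incomplete = 0L))
  prs <- pairs[keep_pair, , drop = FALSE]
  prs <- prs[order(match(prs$patient_id, usable)), , drop = FALSE]
  na_per <- vapply(allele_sets[prs$patient_id], length, integer(1))
  pair_idx <- rep(seq_len(nrow(prs)), na_per)
  allele <- unlist(allele_sets[prs$patient_id], use.names = FALSE)
  kd_mt <- affinity_query(affinities, prs$mt_peptide[pair_idx], allele)
  kd_wt <- affinity_query(affinities, prs$wt_peptide[pair_idx], allele)
  wt_na <- rowsum(as.numeric(is.na(kd_wt)), pair_idx)[, 1] > 0
  wt_fail <- rowsum(as.numeric(!is.na(kd_wt) & kd_wt <= threshold_nM),
                    pair_idx)[, 1] > 0
  wt_ok <- !wt_na & !wt_fail
  mt_ok <- !is.na(kd_mt) & kd_mt < threshold_nM
  incomplete <- as.integer(sum(is.na(kd_mt)) +
                             sum(!is.na(kd_mt) & wt_na[pair_idx]))
  sel <- which(mt_ok & wt_ok[pair_idx])
  if (length(sel) == 0L)
    return(list(neoantigens = empty, incomplete = incomplete))
  neo <- prs[pair_idx[sel], , drop = FALSE]
  neo$allele <- allele[sel]
  neo$kd_mt <- kd_mt[sel]
  neo$kd_wt <- kd_wt[sel]
  neo$dai <- dai(neo$kd_mt, neo$kd_wt)
  rownames(neo) <- NULL
  list(neoantigens = neo, incomplete = incomplete)
}

#' Differential agretopicity index
#'
#' DAI = IC50_WT - IC50_MT on the restricted allele (linear nM scale by
#' default; positive means the mutant binds better). The log10 scale is
#' available for compatibility with alternative conventions.
#'
#' @param kd_mt,kd_wt Mutant / wild-type IC50 on the restricted allele.
#' @param scale `"linear"` (default) or `"log10"`.
#' @return DAI (vectorised).
#' @export
dai <- function(kd_mt, kd_wt, scale = c("linear", "log10")) {
  scale <- match.arg(scale)
  if (scale == "linear") kd_wt - kd_mt else log10(kd_wt) - log10(kd_mt)
}

#' Mean DAI per patient
#'
#' Mean over all of a patient's tumor peptide pairs; patients with no pairs
#' are excluded (DAI undefined).
#'
#' @param neoantigens Data frame with `patient_id` and `dai`.
#' @return Data frame (patient_id, mean_dai).
#' @export
mean_dai <- function(neoantigens) {
  ids <- unique(neoantigens$patient_id)
  data.frame(patient_id = ids,
             mean_dai = vapply(ids, function(p)
               mean(neoantigens$dai[neoantigens$patient_id == p]), numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Mean-split stratification of a numeric score
#'
#' Labels `"high"` iff the value strictly exceeds the cohort mean; ties at
#' the mean go to `"low"`. Used for both the neoantigen quantity and
#' quality models.
#'
#' @param x Numeric scores (>= 2 values).
#' @return Character vector of `"high"`/`"low"` labels (all `"low"`, with a
#'   warning, when every value is equal).
#' @export
mean_split <- function(x) {
  if (length(x) < 2L) stopf("need at least 2 values to stratify")
  if (length(unique(x)) == 1L) {
    warnf("all values equal; every patient labelled 'low'")
    return(rep("low", length(x)))
  }
  ifelse(x > mean(x), "high", "low")
}

#' Neoantigen quantity stratification
#'
#' @param counts Per-patient neoantigen counts.
#' @return `"high"`/`"low"` labels from [mean_split()].
#' @export
quantity_stratify <- function(counts) mean_split(counts)
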
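# Consensus four-digit HLA class I genotyping from multiple callers, and
# the homozygosity-versus-neoantigen-quality association test.

HLA_LOCI <- c("HLA-A", "HLA-B", "HLA-C")
HLA_CALLERS <- c("POLYSOLVER", "OptiType", "PHLAT", "seq2HLA")

# The caller pairs whose exact agreement establishes a consensus genotype.
# PHLAT+seq2HLA alone is deliberately not sufficient.
CONSENSUS_PAIRS <- list(c("POLYSOLVER", "OptiType"),
                        c("POLYSOLVER", "PHLAT"),
                        c("POLYSOLVER", "seq2HLA"),
                        c("OptiType", "PHLAT"),
                        c("OptiType", "seq2HLA"))

norm_genotype <- function(a1, a2) paste(sort(c(a1, a2)), collapse = "/")

#' Consensus HLA class I genotype for one patient
#'
#' A locus genotype is accepted iff at least one of the five recognised
#' caller pairs (POLYSOLVER+OptiType, POLYSOLVER+PHLAT, POLYSOLVER+seq2HLA,
#' OptiType+PHLAT, OptiType+seq2HLA) agrees exactly on the unordered
#' four-digit allele pair. If agreeing pairs support different genotypes,
#' the locus has no consensus. A patient is usable for neoantigen calling
#' only when all three loci reach consensus.
#'
#' @param calls Data frame of caller calls (columns `caller`, `patient_id`,
#'   `locus`, `allele1`, `allele2`).
#' @param patient_id Patient to type.
#' @return A list of class `hla_genotype` with `patient_id`, `alleles`
#'   (six names, or fewer if some locus failed), `by_locus` (named list of
#'   allele pairs or `NA`), `locus_homozygous` (named logical),
#'   `complete` (all three loci typed), `source_callers`. If fewer than two
#'   callers cover the patient an error of class `insufficient_callers` is
#'   raised.
#' @export
consensus_type <- function(calls, patient_id) {
  pc <- calls[calls$patient_id == patient_id, , drop = FALSE]
  callers <- unique(pc$caller)
  if (length(callers) < 2L)
    stop(structure(class = c("insufficient_callers", "error", "condition"),
                   list(message = sprintf("patient %s: fewer than 2 callers", patient_id),
                        call = NULL)))
  by_locus <- stats::setNames(vector("list", length(HLA_LOCI)), HLA_LOCI)
  hom <- stats::setNames(rep(NA, length(HLA_LOCI)), HLA_LOCI)
  used <- character(0)
  for (loc in HLA_LOCI) {
    lc <- pc[pc$locus == loc & !is.na(pc$allele1) & !is.na(pc$allele2), , drop = FALSE]
    geno_by_caller <- stats::setNames(
      vapply(seq_len(nrow(lc)), function(i)
        norm_genotype(lc$allele1[i], lc$allele2[i]), character(1)),
      lc$caller)
    agreed <- character(0)
    pair_callers <- character(0)
    for (pr in CONSENSUS_PAIRS) {
      if (all(pr %in% names(geno_by_caller)) &&
          geno_by_caller[[pr[1]]] == geno_by_caller[[pr[2]]]) {
        agreed <- c(agreed, geno_by_caller[[pr[1]]])
        pair_callers <- c(pair_callers, pr)
      }
    }
    agreed <- unique(agreed)
    if (length(agreed) == 1L) {
      pair <- strsplit(agreed, "/", fixed = TRUE)[[1]]
      by_locus[[loc]] <- pair
      hom[loc] <- pair[1] == pair[2]
      used <- union(used, pair_callers)
    } else {
      by_locus[loc] <- list(NA)  # 0 agreeing pairs, or conflicting genotypes
    }
  }
  typed <- !vapply(by_locus, function(x) all(is.na(x)), logical(1))
  structure(list(patient_id = patient_id,
                 alleles = unlist(by_locus[typed], use.names = FALSE),
                 by_locus = by_locus,
                 locus_homozygous = hom,
                 complete = all(typed),
                 source_callers = used),
            class = "hla_genotype")
}

#' @export
print.hla_genotype <- function(x, ...) {
  cat(sprintf("HLA genotype for %s (%s)\n", x$patient_id,
              if (x$complete) "complete" else "incomplete"))
  for (loc in names(x$by_locus)) {
    g <- x$by_locus[[loc]]
    cat(sprintf("  %s: %s\n", loc,
                if (all(is.na(g))) "no consensus" else paste(g, collapse = " / ")))
  }
  invisible(x)
}

#' Consensus genotypes for a whole cohort
#'
#' @param calls Caller table as in [consensus_type()].
#' @return Named list of `hla_genotype` objects (patients with < 2 callers
#'   are skipped with a warning).
#' @export
consensus_type_cohort <- function(calls) {
  ids <- unique(calls$patient_id)
  out <- list()
  for (p in ids) {
    g <- tryCatch(consensus_type(calls, p),
                  insufficient_callers = function(e) NULL)
    if (is.null(g)) warnf("patient %s skipped: fewer than 2 callers", p)
    else out[[p]] <- g
  }
  out
}

#' Is any HLA class I locus homozygous?
#'
#' @param genotype An `hla_genotype`.
#' @return `TRUE` if any typed locus carries two identical four-digit
#'   alleles.
#' @export
any_homozygous <- function(genotype) {
  any(genotype$locus_homozygous, na.rm = TRUE)
}

#' HLA homozygosity versus neoantigen-quality association
#'
#' Builds the 2x2 table of any-locus homozygosity against quality group and
#' tests, with a one-sided Fisher exact test, whether homozygosity is more
#' frequent among low-quality patients.
#'
#' @param homozygous Logical vector (any locus homozygous), one per patient,
#'   or a list of `hla_genotype` objects.
#' @param quality_labels Character vector `"high"`/`"low"`, aligned with
#'   `homozygous`.
#' @return List with `table` (2x2), `odds_ratio`, `p`.
#' @export
homozygosity_association <- function(homozygous, quality_labels) {
  if (is.list(homozygous) && !is.logical(homozygous))
    homozygous <- vapply(homozygous, any_homozygous, logical(1))
  if (!all(quality_labels %in% c("high", "low")))
    stopf("quality labels must be 'high'/'low'")
  if (!any(quality_labels == "high") || !any(quality_labels == "low"))
    stopf("undefined test: a quality group is empty")
  tab <- matrix(c(sum(homozygous & quality_labels == "low"),
                  sum(!homozygous & quality_labels == "low"),
                  sum(homozygous & quality_labels == "high"),
                  sum(!homozygous & quality_labels == "high")),
                nrow = 2, byrow = TRUE,
                dimnames = list(group = c("low", "high"),
                                homozygous = c("yes", "no")))
  ft <- stats::fisher.test(tab, alternative = "greater")
  list(table = tab, odds_ratio = unname(ft$estimate), p = ft$p.value)
}
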
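# Seeded synthetic-cohort generator. Produces complete cohorts with the
# statistical structure the pipeline assumes — missense mutations whose
# mutant 9-mers may share motifs with an "immunogenic-like" epitope set,
# binding affinities with a mutant shift, multi-caller HLA tables, survival
# driven by the true quality x infiltration stratum, expression with spiked
# signature genes and methylation anti-correlated with expression — plus
# ground-truth labels, so every pipeline stage can be validated end to end
# without external data.

rand_aa <- function(n) paste(sample(AA_ALPHABET, n, replace = TRUE),
                             collapse = "")

#' Synthetic cohort configuration
#'
#' Defaults describe a desk-scale validation cohort: 120 patients, Poisson
#' mutation load, lognormal IC50s with the mutant distribution shifted
#' toward strong binding for a `p_binder` fraction of designated peptides,
#' an epitope database whose "positive high" members donate sequence motifs
#' to the binder peptides of true high-quality patients
#' (`motif_strength`), exponential survival whose hazard is multiplied per
#' true quality x infiltration stratum, expression with the 30-gene
#' signature shifted in infiltrated patients, and promoter methylation
#' anti-correlated with expression.
#'
#' @param n_patients Cohort size.
#' @param mutations_per_patient Poisson mean of missense mutations.
#' @param context_length Protein-context length around each substitution.
#' @param alleles_per_locus HLA allele pool size per locus.
#' @param homozygosity_rate Probability a locus is homozygous.
#' @param caller_disagreement Probability a caller perturbs one allele.
#' @param p_binder Probability a mutation's designated mutant 9-mer is a
#'   strong binder (IC50 below 500 nM) on one patient allele.
#' @param ic50 List of lognormal (meanlog, sdlog) parameters for wild-type
#'   peptides, mutant binders and mutant non-binders.
#' @param epitope_db_size Number of epitopes.
#' @param positive_fraction Fraction of epitopes labelled "positive high".
#' @param motif_strength Probability that a high-quality patient's binder
#'   peptide is copied (with one substitution) from a positive epitope.
#' @param quality_fraction,infiltration_fraction True-label prevalences.
#' @param baseline_rate Exponential baseline hazard (per day).
#' @param hazard_multipliers Named multipliers for Q+I+, Q+I-, Q-I+, Q-I-.
#' @param censoring_rate Expected fraction censored under baseline hazard.
#' @param n_genes,signature_size,signature_shift Expression model: total
#'   genes, signature genes, z-shift of signature genes in infiltrated
#'   patients.
#' @param n_meth_genes Genes given one promoter probe each.
#' @param methylation_coupling Strength of the beta-expression
#'   anti-correlation.
#' @param seed Integer master seed (fans out to fixed per-component
#'   substreams).
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 120L,
                          mutations_per_patient = 12,
                          context_length = 17L,
                          alleles_per_locus = 4L,
                          homozygosity_rate = 0.15,
                          caller_disagreement = 0.02,
                          p_binder = 0.5,
                          ic50 = list(wt = c(meanlog = log(5000), sdlog = 0.35),
                                      mt_binder = c(meanlog = log(150), sdlog = 0.25),
                                      mt_nonbinder = c(meanlog = log(8000), sdlog = 0.5)),
                          epitope_db_size = 80L,
                          positive_fraction = 0.5,
                          motif_strength = 0.9,
                          quality_fraction = 0.5,
                          infiltration_fraction = 0.5,
                          baseline_rate = 1 / 500,
                          hazard_multipliers = c("Q+I+" = 0.4, "Q+I-" = 1,
                                                 "Q-I+" = 1, "Q-I-" = 1),
                          censoring_rate = 0.3,
                          n_genes = 500L,
                          signature_size = 30L,
                          signature_shift = 1.5,
                          n_meth_genes = 200L,
                          methylation_coupling = 0.6,
                          seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(n_patients >= 2L, mutations_per_patient > 0,
            context_length >= 9L,
            homozygosity_rate >= 0, homozygosity_rate <= 1,
            p_binder >= 0, p_binder <= 1,
            motif_strength >= 0, motif_strength <= 1,
            baseline_rate > 0, all(hazard_multipliers > 0),
            censoring_rate >= 0, censoring_rate < 1)
  if (!setequal(names(hazard_multipliers), c("Q+I+", "Q+I-", "Q-I+", "Q-I-")))
    stopf("hazard_multipliers must name the four strata")
  structure(cfg, class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("Synthetic cohort config: %d patients, ~%g mutations each, seed %d\n",
              x$n_patients, x$mutations_per_patient, x$seed))
  invisible(x)
}

# Fixed substream offsets so adding a component never perturbs the others.
.SUBSTREAMS <- c(labels = 11L, hla = 23L, epitopes = 37L, mutations = 53L,
                 affinities = 67L, survival = 79L, expression = 97L,
                 methylation = 113L)

substream <- function(seed, component) {
  set.seed((seed + .SUBSTREAMS[[component]]) %% .Machine$integer.max)
}

#' Simulate a synthetic cohort
#'
#' @param config A [cohort_config()].
#' @return Object of class `nq_cohort`: data frames `mutations`,
#'   `affinities`, `hla_calls`, `epitopes`, `clinical`; matrices
#'   `expression`, `methylation`; `probe_gene` map; `signatures` (named
#'   list, the CD8 signature first); and `truth` (true strata, labels,
#'   genotypes, signature genes, config echo).
#' @export
simulate_cohort <- function(config = cohort_config()) {
  cfg <- config
  ids <- sprintf("P%03d", seq_len(cfg$n_patients))

  substream(cfg$seed, "labels")
  q_true <- stats::rbinom(cfg$n_patients, 1L, cfg$quality_fraction) == 1L
  i_true <- stats::rbinom(cfg$n_patients, 1L, cfg$infiltration_fraction) == 1L
  stratum <- paste0(ifelse(q_true, "Q+", "Q-"), ifelse(i_true, "I+", "I-"))
  if (length(unique(stratum)) < 2L && cfg$n_patients >= 4L)
    stopf("degenerate configuration: a single stratum was generated")

  # ---- HLA genotypes and caller tables -------------------------------
  substream(cfg$seed, "hla")
  pool <- lapply(HLA_LOCI, function(loc) {
    sprintf("%s*%02d:%02d", loc, seq_len(cfg$alleles_per_locus),
            seq_len(cfg$alleles_per_locus))
  })
  names(pool) <- HLA_LOCI
  true_geno <- lapply(ids, function(p) {
    g <- lapply(HLA_LOCI, function(loc) {
      a1 <- sample(pool[[loc]], 1L)
      if (stats::runif(1) < cfg$homozygosity_rate) c(a1, a1)
      else c(a1, sample(setdiff(pool[[loc]], a1), 1L))
    })
    names(g) <- HLA_LOCI
    g
  })
  names(true_geno) <- ids
  calls <- list()
  for (p in ids) for (cl in HLA_CALLERS) for (loc in HLA_LOCI) {
    g <- true_geno[[p]][[loc]]
    if (stats::runif(1) < cfg$caller_disagreement) {
      slot <- sample(1:2, 1L)
      g[slot] <- sample(setdiff(pool[[loc]], g[slot]), 1L)
    }
    calls[[length(calls) + 1L]] <-
      data.frame(caller = cl, patient_id = p, locus = loc,
                 allele1 = g[1], allele2 = g[2], stringsAsFactors = FALSE)
  }
  hla_calls <- do.call(rbind, calls)

  # ---- epitope database ----------------------------------------------
  substream(cfg$seed, "epitopes")
  n_pos <- round(cfg$epitope_db_size * cfg$positive_fraction)
  ep_len <- sample(9:12, cfg$epitope_db_size, replace = TRUE)
  ep_seq <- vapply(ep_len, rand_aa, character(1))
  assay <- rep(c("T cell", "MHC ligand"), length.out = cfg$epitope_db_size)
  qualitative <- c(rep("positive high", n_pos),
                   rep("negative", cfg$epitope_db_size - n_pos))
  epitopes <- data.frame(sequence = ep_seq, assay_type = assay,
                         qualitative = qualitative, stringsAsFactors = FALSE)
  pos_seqs <- epitopes$sequence[epitopes$qualitative == "positive high"]

  # ---- mutations ------------------------------------------------------
  substream(cfg$seed, "mutations")
  center <- (cfg$context_length + 1L) %/% 2L
  n_mut_per <- stats::rpois(cfg$n_patients, cfg$mutations_per_patient)
  M <- sum(n_mut_per)
  mut_patient <- rep(ids, n_mut_per)
  mut_qtrue <- rep(q_true, n_mut_per)
  binder_flag <- stats::runif(M) < cfg$p_binder
  motif_flag <- binder_flag & mut_qtrue & stats::runif(M) < cfg$motif_strength
  ctx_v <- character(M); ref_v <- character(M); alt_v <- character(M)
  for (k in seq_len(M)) {
    if (motif_flag[k]) {
      e <- sample(pos_seqs, 1L)
      start <- sample(nchar(e) - 8L, 1L)
      mt9 <- substr(e, start, start + 8L)
      alt_v[k] <- substr(mt9, 5L, 5L)
      ref_v[k] <- sample(setdiff(AA_ALPHABET, alt_v[k]), 1L)
      wt9 <- mt9
      substr(wt9, 5L, 5L) <- ref_v[k]
      ctx_v[k] <- paste0(rand_aa(center - 5L), wt9,
                         rand_aa(cfg$context_length - center - 4L))
    } else {
      ctx_v[k] <- rand_aa(cfg$context_length)
      ref_v[k] <- substr(ctx_v[k], center, center)
      alt_v[k] <- sample(setdiff(AA_ALPHABET, ref_v[k]), 1L)
    }
  }
  mutations <- data.frame(patient_id = mut_patient,
                          gene = sprintf("G%04d", sample(cfg$n_genes, M,
                                                         replace = TRUE)),
                          protein_context = ctx_v, position = center,
                          ref = ref_v, alt = alt_v, stringsAsFactors = FALSE)

  # ---- affinities -----------------------------------------------------
  # Covers every enumerated (peptide, patient-allele) combination. The
  # designated mutant 9-mer (the center window) of a binder mutation draws
  # from the strong-binder distribution on one random patient allele; all
  # other mutant windows and alleles are non-binders; wild-type peptides
  # draw from the weak-binder distribution everywhere.
  substream(cfg$seed, "affinities")
  rln <- function(n, par) stats::rlnorm(n, par[["meanlog"]], par[["sdlog"]])
  L <- cfg$context_length
  nw <- L - 8L                       # windows per mutation (all cover center)
  starts <- seq_len(nw)
  mt_ctx <- mutations$protein_context
  substr(mt_ctx, center, center) <- mutations$alt   # vectorised replace
  pep_list <- vector("list", M); allele_list <- vector("list", M)
  val_list <- vector("list", M)
  patient_alleles <- lapply(true_geno, function(g) unique(unlist(g)))
  for (k in seq_len(M)) {
    wt_p <- substring(mutations$protein_context[k], starts, starts + 8L)
    mt_p <- substring(mt_ctx[k], starts, starts + 8L)
    offs <- center - starts
    alleles <- patient_alleles[[mut_patient[k]]]
    restricted <- sample(alleles, 1L)
    na <- length(alleles)
    al <- rep(alleles, times = nw)
    strong <- binder_flag[k] & rep(offs == 4L, each = na) & al == restricted
    pep_list[[k]] <- c(rep(mt_p, each = na), rep(wt_p, each = na))
    allele_list[[k]] <- c(al, al)
    val_list[[k]] <- c(ifelse(strong, rln(nw * na, cfg$ic50$mt_binder),
                              rln(nw * na, cfg$ic50$mt_nonbinder)),
                       rln(nw * na, cfg$ic50$wt))
  }
  aff <- data.frame(peptide = unlist(pep_list),
                    allele = unlist(allele_list),
                    ic50_nM = round(unlist(val_list), 4),
                    stringsAsFactors = FALSE)
  aff <- aff[!duplicated(paste(aff$peptide, aff$allele, sep = "|")), ,
             drop = FALSE]

  # ---- survival -------------------------------------------------------
  # Independent uniform censoring: each patient is censored with
  # probability censoring_rate, at a uniform point of its event time, so
  # the censored fraction is the same in every stratum.
  substream(cfg$seed, "survival")
  mult <- cfg$hazard_multipliers[stratum]
  t_event <- stats::rexp(cfg$n_patients, rate = cfg$baseline_rate * mult)
  censored <- stats::runif(cfg$n_patients) < cfg$censoring_rate
  obs <- ifelse(censored, stats::runif(cfg$n_patients) * t_event, t_event)
  t_cens <- ifelse(censored, obs, Inf)
  mut_load <- vapply(ids, function(p) sum(mutations$patient_id == p),
                     integer(1))
  clinical <- data.frame(patient_id = ids,
                         survival_days = round(obs, 2),
                         event = as.integer(t_event <= t_cens),
                         age = round(stats::rnorm(cfg$n_patients, 60, 10)),
                         gender = sample(c("female", "male"),
                                         cfg$n_patients, replace = TRUE),
                         mutation_load = unname(mut_load),
                         stringsAsFactors = FALSE)

  # ---- expression with spiked signature ------------------------------
  substream(cfg$seed, "expression")
  genes <- sprintf("G%04d", seq_len(cfg$n_genes))
  expr <- matrix(stats::rnorm(cfg$n_genes * cfg$n_patients), cfg$n_genes,
                 cfg$n_patients, dimnames = list(genes, ids))
  sig_genes <- genes[seq_len(cfg$signature_size)]
  expr[sig_genes, i_true] <- expr[sig_genes, i_true] + cfg$signature_shift
  signatures <- list(CD8_T_cells = sig_genes)

  # ---- promoter methylation anti-correlated with expression ----------
  substream(cfg$seed, "methylation")
  mg <- genes[seq_len(cfg$n_meth_genes)]
  beta <- stats::plogis(stats::qlogis(0.35) -
                          cfg$methylation_coupling * expr[mg, , drop = FALSE] +
                          matrix(stats::rnorm(length(mg) * cfg$n_patients, 0, 0.3),
                                 length(mg), cfg$n_patients))
  probes <- sprintf("cg%05d", seq_along(mg))
  rownames(beta) <- probes
  probe_gene <- data.frame(probe = probes, gene = mg,
                           stringsAsFactors = FALSE)

  structure(list(mutations = mutations, affinities = aff,
                 hla_calls = hla_calls, epitopes = epitopes,
                 clinical = clinical, expression = expr,
                 methylation = beta, probe_gene = probe_gene,
                 signatures = signatures,
                 truth = list(patient_id = ids, stratum = stratum,
                              quality = ifelse(q_true, "high", "low"),
                              infiltration = ifelse(i_true, "high", "low"),
                              n_mutations = nrow(mutations),
                              n_binder_mutations = sum(binder_flag),
                              genotypes = true_geno,
                              signature_genes = sig_genes,
                              hazard_multipliers = cfg$hazard_multipliers,
                              seed = cfg$seed)),
            class = "nq_cohort")
}

#' @export
print.nq_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d patients, %d mutations, %d affinity entries, %d epitopes\n",
              nrow(x$clinical), nrow(x$mutations), nrow(x$affinities),
              nrow(x$epitopes)))
  invisible(x)
}

#' Write a cohort to disk in the package's file formats
#'
#' @param cohort An `nq_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(cohort$mutations, file.path(dir, "mutations.tsv"))
  write_tsv(cohort$affinities, file.path(dir, "affinities.tsv"))
  write_tsv(cohort$hla_calls, file.path(dir, "hla_calls.tsv"))
  write_tsv(cohort$epitopes, file.path(dir, "epitopes.tsv"))
  write_tsv(cohort$clinical, file.path(dir, "clinical.tsv"))
  write_matrix(cohort$expression, file.path(dir, "expression.tsv"),
               id_col = "gene")
  write_matrix(cohort$methylation, file.path(dir, "methylation.tsv"),
               id_col = "probe")
  write_tsv(cohort$probe_gene, file.path(dir, "probe_gene.tsv"))
  write_gmt(cohort$signatures, file.path(dir, "signatures.gmt"))
  truth <- cohort$truth
  truth$genotypes <- lapply(truth$genotypes, function(g) lapply(g, as.list))
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort previously written by [write_cohort()]
#'
#' @param dir Cohort directory.
#' @return An `nq_cohort` (ground-truth genotypes as nested lists).
#' @export
read_cohort <- function(dir) {
  truth <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                               simplifyVector = TRUE)
  structure(list(mutations = read_mutations(file.path(dir, "mutations.tsv")),
                 affinities = read_tsv(file.path(dir, "affinities.tsv")),
                 hla_calls = read_hla_calls(file.path(dir, "hla_calls.tsv")),
                 epitopes = read_epitopes(file.path(dir, "epitopes.tsv")),
                 clinical = read_clinical(file.path(dir, "clinical.tsv")),
                 expression = read_matrix(file.path(dir, "expression.tsv")),
                 methylation = read_matrix(file.path(dir, "methylation.tsv")),
                 probe_gene = read_tsv(file.path(dir, "probe_gene.tsv")),
                 signatures = read_gmt(file.path(dir, "signatures.gmt")),
                 truth = truth),
            class = "nq_cohort")
}

#' Run the quality pipeline on a cohort
#'
#' Convenience wrapper chaining consensus HLA typing, peptide-pair
#' enumeration, the stringent affinity filter, NRP scoring under fixed
#' parameters (or a grid fit), mean-split quality labels, CD8-signature NES
#' median-split labels, and the four-group survival stratification.
#'
#' @param cohort An `nq_cohort`.
#' @param params [nq_params()] for fixed-parameter scoring (default the
#'   validated setting a = 21, k = 1.6).
#' @param grid Optional [nq_grid()]; when supplied the parameters are
#'   trained by grid search instead.
#' @return List with `genotypes`, `neoantigens`, `scored`, `quality`
#'   (patient table with labels), `nes_labels`, `four_group`, and `fit`
#'   (the `nq_fit` when a grid was used).
#' @export
cohort_pipeline <- function(cohort, params = nq_params(21, 1.6),
                            grid = NULL) {
  genotypes <- suppressWarnings(consensus_type_cohort(cohort$hla_calls))
  pairs <- enumerate_pairs_all(cohort$mutations)
  lookup <- affinity_lookup(cohort$affinities)
  called <- suppressWarnings(
    call_neoantigens_cohort(pairs, lookup, genotypes))
  neo <- called$neoantigens
  clinical <- cohort$clinical
  out <- list(genotypes = genotypes, neoantigens = neo)
  if (!is.null(grid)) {
    fit <- nq_fit(neo, clinical, cohort$epitopes, grid = grid)
    out$fit <- fit
    quality <- fit$scores
  } else {
    scored <- suppressWarnings(
      score_neoantigens(neo, cohort$epitopes, params))
    out$scored <- scored
    quality <- patient_quality(scored, clinical$patient_id)
    quality$label <- mean_split(quality$quality)
  }
  out$quality <- quality
  nes_vals <- nes_matrix(cohort$expression, cohort$signatures)[1, ]
  out$nes <- nes_vals
  out$nes_labels <- enrichment_stratify(nes_vals)
  out$four_group <- four_group_stratify(
    quality$label[match(clinical$patient_id, quality$patient_id)],
    out$nes_labels[match(clinical$patient_id, colnames(cohort$expression))],
    clinical$survival_days, clinical$event)
  out
}

#' Recovery metrics of pipeline outputs against ground truth
#'
#' @param cohort An `nq_cohort` with `truth`.
#' @param quality_labels Named or ordered `"high"`/`"low"` labels from the
#'   pipeline (order of `cohort$clinical$patient_id`).
#' @param nes_labels Optional infiltration labels (same order).
#' @param de_results Optional [diff_expression()] table; sensitivity/FDR
#'   are computed against the true signature genes.
#' @param cox_hr Optional estimated hazard ratio for the quality group;
#'   compared with the true Q+I+ multiplier.
#' @return List of agreement/recovery metrics.
#' @export
oracle_report <- function(cohort, quality_labels, nes_labels = NULL,
                          de_results = NULL, cox_hr = NULL) {
  truth <- cohort$truth
  if (length(quality_labels) != length(truth$patient_id))
    stopf("mismatched patient ids between labels and truth")
  out <- list(quality_agreement = mean(quality_labels == truth$quality))
  if (!is.null(nes_labels))
    out$infiltration_agreement <- mean(nes_labels == truth$infiltration)
  if (!is.null(de_results)) {
    pos <- de_results$gene[de_results$significant]
    truth_pos <- truth$signature_genes
    out$de_sensitivity <- mean(truth_pos %in% pos)
    out$de_fdr <- if (length(pos)) mean(!pos %in% truth_pos) else 0
  }
  if (!is.null(cox_hr)) {
    true_hr <- unname(truth$hazard_multipliers["Q+I+"])
    out$cox_hr_error <- abs(log(cox_hr) - log(true_hr))
  }
  out
}
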
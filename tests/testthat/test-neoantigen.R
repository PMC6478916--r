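# Peptide-pair enumeration, the stringent affinity filter, quantity
# stratification and DAI.

test_that("pair enumeration yields every fully-contained window over the substitution", {
  # interior residue of a 40-aa context: all 9 windows fit
  ctx <- strrep("ACDEFGHIKL", 4)
  m <- toy_mutation(context = ctx, position = 20, alt = "W")
  pairs <- enumerate_pairs(m)
  expect_equal(nrow(pairs), 9L)
  expect_setequal(pairs$window_offset, 0:8)
  # each pair differs at exactly the offset position
  for (i in seq_len(nrow(pairs))) {
    diffs <- which(strsplit(pairs$mt_peptide[i], "")[[1]] !=
                     strsplit(pairs$wt_peptide[i], "")[[1]])
    expect_identical(diffs, pairs$window_offset[i] + 1L)
    expect_identical(substr(pairs$mt_peptide[i], diffs, diffs), "W")
  }

  # substitution at position 1: only the offset-0 window exists
  m1 <- toy_mutation(context = ctx, position = 1, alt = "W")
  p1 <- enumerate_pairs(m1)
  expect_equal(nrow(p1), 1L)
  expect_identical(p1$window_offset, 0L)

  # 9-aa context with the substitution at position 5: exact fit
  m2 <- toy_mutation(context = "ACDEFGHIK", position = 5, alt = "W")
  expect_equal(nrow(enumerate_pairs(m2)), 1L)

  # too-short context: zero pairs with warning
  m3 <- toy_mutation(context = "ACDEFGHI", position = 3, alt = "W")
  expect_warning(p3 <- enumerate_pairs(m3), "too short")
  expect_equal(nrow(p3), 0L)
})

test_that("the affinity filter keeps exactly MT<500 on the allele AND WT>500 on all alleles", {
  alleles <- c("HLA-A*02:01", "HLA-A*01:01", "HLA-B*07:02", "HLA-B*08:01",
               "HLA-C*07:01", "HLA-C*04:01")
  pairs <- data.frame(patient_id = "P1", gene = "G1", window_offset = 0L,
                      mt_peptide = "AAAAAAAAW", wt_peptide = "AAAAAAAAA",
                      stringsAsFactors = FALSE)
  rows <- c(lapply(alleles, function(al) list("AAAAAAAAA", al, 600)),
            lapply(alleles, function(al) list("AAAAAAAAW", al, 4000)))
  rows[[7]] <- list("AAAAAAAAW", "HLA-A*02:01", 400)   # MT binder on A*02:01
  lk <- toy_affinities(rows)
  res <- call_neoantigens(pairs, lk, alleles)
  expect_equal(nrow(res$neoantigens), 1L)
  expect_identical(res$neoantigens$allele, "HLA-A*02:01")
  expect_equal(res$neoantigens$kd_mt, 400)
  expect_equal(res$neoantigens$dai, 600 - 400)

  # WT 450 on one allele only -> rejected everywhere
  rows2 <- rows
  rows2[[3]] <- list("AAAAAAAAA", "HLA-B*07:02", 450)
  expect_equal(nrow(call_neoantigens(pairs, toy_affinities(rows2),
                                     alleles)$neoantigens), 0L)

  # MT exactly 500 -> rejected (strict <)
  rows3 <- rows
  rows3[[7]] <- list("AAAAAAAAW", "HLA-A*02:01", 500)
  expect_equal(nrow(call_neoantigens(pairs, toy_affinities(rows3),
                                     alleles)$neoantigens), 0L)

  # missing affinity -> skipped and tallied, never defaulted
  rows4 <- rows[-1]
  res4 <- call_neoantigens(pairs, toy_affinities(rows4), alleles)
  expect_equal(nrow(res4$neoantigens), 0L)
  expect_gt(res4$incomplete, 0L)
})

test_that("filter calls equal exhaustive checking on random small cohorts", {
  set.seed(11)
  alleles <- sprintf("HLA-A*%02d:01", 1:4)
  for (rep in 1:5) {
    n_mut <- sample(3:8, 1)
    pairs <- do.call(rbind, lapply(seq_len(n_mut), function(i) {
      ctx <- paste(sample(AA <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]],
                          12, replace = TRUE), collapse = "")
      m <- toy_mutation(patient = "P1", context = ctx, position = 6,
                        alt = sample(setdiff(AA, substr(ctx, 6, 6)), 1))
      enumerate_pairs(m)
    }))
    peps <- unique(c(pairs$mt_peptide, pairs$wt_peptide))
    aff <- expand.grid(peptide = peps, allele = alleles,
                       stringsAsFactors = FALSE)
    aff$ic50_nM <- exp(runif(nrow(aff), log(50), log(5000)))
    lk <- affinity_lookup(aff)
    got <- call_neoantigens(pairs, lk, alleles)$neoantigens
    # brute force over every (pair, allele)
    want <- 0L
    for (i in seq_len(nrow(pairs))) for (al in alleles) {
      mt <- aff$ic50_nM[aff$peptide == pairs$mt_peptide[i] & aff$allele == al]
      wt_all <- aff$ic50_nM[aff$peptide == pairs$wt_peptide[i]]
      if (mt < 500 && all(wt_all > 500)) want <- want + 1L
    }
    expect_equal(nrow(got), want)
  }
})

test_that("repeated calling is idempotent and threshold tightening shrinks the set", {
  set.seed(12)
  alleles <- sprintf("HLA-A*%02d:01", 1:2)
  ctx <- "ACDEFGHIKLMNPQRST"
  m <- toy_mutation(context = ctx, position = 9, alt = "W")
  pairs <- enumerate_pairs(m)
  peps <- unique(c(pairs$mt_peptide, pairs$wt_peptide))
  aff <- expand.grid(peptide = peps, allele = alleles,
                     stringsAsFactors = FALSE)
  aff$ic50_nM <- exp(runif(nrow(aff), log(100), log(2000)))
  lk <- affinity_lookup(aff)
  a1 <- call_neoantigens(pairs, lk, alleles)$neoantigens
  a2 <- call_neoantigens(pairs, lk, alleles)$neoantigens
  expect_identical(a1, a2)
  # at any threshold the calls equal the brute-force rule
  for (thr in c(300, 500, 800)) {
    got <- call_neoantigens(pairs, lk, alleles,
                            threshold_nM = thr)$neoantigens
    want <- 0L
    for (i in seq_len(nrow(pairs))) for (al in alleles) {
      mt <- aff$ic50_nM[aff$peptide == pairs$mt_peptide[i] & aff$allele == al]
      wt_all <- aff$ic50_nM[aff$peptide == pairs$wt_peptide[i]]
      if (mt < thr && all(wt_all > thr)) want <- want + 1L
    }
    expect_equal(nrow(got), want)
  }
})

test_that("the cohort-level caller equals the per-patient filter", {
  co <- simulate_cohort(cohort_config(n_patients = 15, seed = 3))
  genotypes <- suppressWarnings(consensus_type_cohort(co$hla_calls))
  pairs <- enumerate_pairs_all(co$mutations)
  lk <- affinity_lookup(co$affinities)
  bulk <- suppressWarnings(call_neoantigens_cohort(pairs, lk, genotypes))
  per <- list(); inc <- 0L
  for (p in unique(pairs$patient_id)) {
    g <- genotypes[[p]]
    if (is.null(g) || !g$complete) next
    r <- call_neoantigens(pairs[pairs$patient_id == p, , drop = FALSE],
                          lk, g$alleles)
    per[[p]] <- r$neoantigens
    inc <- inc + r$incomplete
  }
  per <- do.call(rbind, c(per, list(make.row.names = FALSE)))
  expect_equal(nrow(bulk$neoantigens), nrow(per))
  expect_identical(bulk$neoantigens$mt_peptide, per$mt_peptide)
  expect_identical(bulk$neoantigens$allele, per$allele)
  expect_equal(bulk$neoantigens$kd_mt, per$kd_mt)
  expect_identical(bulk$incomplete, inc)
})

test_that("quantity stratification splits at the mean with ties going low", {
  expect_identical(quantity_stratify(c(0, 2, 4)), c("low", "low", "high"))
  expect_warning(lab <- quantity_stratify(c(5, 5, 5)), "all values equal")
  expect_identical(lab, c("low", "low", "low"))
  expect_identical(quantity_stratify(c(0, 10)), c("low", "high"))
})

test_that("DAI is WT minus MT and mean DAI averages a patient's pairs", {
  expect_equal(dai(100, 600), 500)
  expect_equal(dai(250, 250), 0)
  neo <- data.frame(patient_id = c("P1", "P1"), dai = c(500, -100))
  expect_equal(mean_dai(neo)$mean_dai, 200)
  expect_equal(dai(10, 1000, scale = "log10"), 2)
})
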
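# Alignment scoring, recognition sigmoid, amplitude, NRP and the
# immunogenicity-similarity comparison.

test_that("self-alignment sums diagonal BLOSUM62 entries", {
  B <- blosum62()
  expect_equal(align_score("AAAAAAAAA", "AAAAAAAAA"), 9 * B["A", "A"])
  expect_equal(align_score("AAAAAAAAA", "AAAAAAAAA"), 36)
  pep <- "KLMNPQRST"
  expect_equal(align_score(pep, pep),
               sum(B[cbind(strsplit(pep, "")[[1]], strsplit(pep, "")[[1]])]))
})

test_that("alignment equals brute-force max over offsets and flags short epitopes", {
  set.seed(3)
  B <- blosum62()
  aa <- rownames(B)
  for (rep in 1:20) {
    pep <- paste(sample(aa, 9, replace = TRUE), collapse = "")
    epi <- paste(sample(aa, sample(9:15, 1), replace = TRUE), collapse = "")
    expect_equal(align_score(pep, epi), brute_align(pep, epi, B),
                 tolerance = 1e-10)
  }
  expect_true(is.na(align_score("AAAAAAAAA", "AAAAAAAA")))  # length 8
})

test_that("vectorised score matrix agrees with the scalar implementation", {
  set.seed(4)
  aa <- rownames(blosum62())
  peps <- replicate(5, paste(sample(aa, 9, replace = TRUE), collapse = ""))
  epis <- c(replicate(4, paste(sample(aa, sample(9:14, 1), replace = TRUE),
                               collapse = "")), "AAAAAAAA")
  S <- neoquality:::align_score_matrix(peps, epis)
  for (i in seq_along(peps)) for (j in seq_along(epis)) {
    expect_equal(S[i, j], as.numeric(align_score(peps[i], epis[j])))
  }
})

test_that("recognition sigmoid hits its midpoint, saturates, and matches the partition form on one epitope", {
  # s* == a gives R = 0.5
  p <- nq_params(a = 36, k = 1)
  expect_equal(recognition("AAAAAAAAA", "AAAAAAAAA", p), 0.5)
  # large k with s* > a saturates to 1
  p2 <- nq_params(a = 20, k = 50)
  expect_equal(recognition("AAAAAAAAA", "AAAAAAAAA", p2), 1, tolerance = 1e-9)
  # single-epitope partition-sum equals max-logistic on a (a, k) grid
  for (a in seq(10, 40, length.out = 10)) {
    for (k in seq(0.2, 5, length.out = 10)) {
      pm <- nq_params(a = a, k = k, aggregation = "max-logistic")
      pp <- nq_params(a = a, k = k, aggregation = "partition-sum")
      expect_equal(recognition(scores = 30, params = pm),
                   recognition(scores = 30, params = pp),
                   tolerance = 1e-12)
    }
  }
  expect_warning(r <- recognition("AAAAAAAAA", "AAAAAAAA", p), "no comparable")
  expect_true(is.na(r))
})

test_that("R is monotone in s* and k; A is monotone in its constants", {
  p <- nq_params(a = 21, k = 1.6)
  s <- seq(0, 50, by = 1)
  r <- vapply(s, function(si) recognition(scores = si, params = p), numeric(1))
  expect_true(all(diff(r) >= 0))
  ks <- seq(0.1, 8, by = 0.1)
  rk <- vapply(ks, function(k)
    recognition(scores = 30, params = nq_params(a = 21, k = k)), numeric(1))
  expect_true(all(diff(rk) >= 0))   # s* > a: increasing in k
  # A decreasing in kd_mt, increasing in kd_wt while eps*kd_wt < 1
  mt <- seq(10, 490, by = 10)
  expect_true(all(diff(amplitude(mt, 1000)) < 0))
  wt <- seq(600, 3000, by = 100)   # eps 3e-4 * 3000 < 1
  expect_true(all(diff(amplitude(100, wt)) > 0))
})

test_that("amplitude follows the pseudo-count formula", {
  expect_equal(amplitude(100, 100, eps_over_L = 0), 1)
  expect_equal(amplitude(50, 500, eps_over_L = 3e-4), 10 / 1.15)
  expect_equal(amplitude(50, 500), 8.6957, tolerance = 1e-4)
  expect_error(amplitude(-1, 100), "positive")
})

test_that("NRP factorises: substituting the matrix rescales R but leaves A unchanged", {
  neo <- data.frame(patient_id = "P1", mt_peptide = "KLMNPQRST",
                    kd_mt = 100, kd_wt = 1000, stringsAsFactors = FALSE)
  s1 <- score_neoantigens(neo, "KLMNPQRST", nq_params(a = 50, k = 0.05))
  s2 <- score_neoantigens(neo, "KLMNPQRST",
                          nq_params(a = 50, k = 0.05, matrix = 2 * blosum62()))
  expect_equal(s1$A, s2$A)
  expect_false(isTRUE(all.equal(s1$R, s2$R)))
  expect_equal(s1$nrp, s1$A * s1$R)
})

test_that("patient quality is the mean NRP, invariant to order, zero with no neoantigens", {
  scored <- data.frame(patient_id = c("P1", "P1", "P2"),
                       nrp = c(2, 4, 7), stringsAsFactors = FALSE)
  q <- patient_quality(scored, patients = c("P1", "P2", "P3"))
  expect_equal(q$quality, c(3, 7, 0))
  expect_equal(q$n_neoantigens, c(2L, 1L, 0L))
  qs <- patient_quality(scored[c(3, 1, 2), ], patients = c("P1", "P2", "P3"))
  expect_equal(qs$quality, q$quality)
})

test_that("similarity comparison uses exact MWW behaviour on small groups", {
  eps <- data.frame(sequence = c("AAAAAAAAA", "KLMNPQRST"),
                    assay_type = c("T cell", "T cell"),
                    qualitative = c("positive high", "positive high"),
                    stringsAsFactors = FALSE)
  # one peptide per group: exact two-sided MWW p is 1
  res <- iedb_similarity_comparison("AAAAAAAAA", "KLMNPQRST", eps)
  expect_equal(res$p, 1)

  # identical distributions give p near 1
  res2 <- suppressWarnings(iedb_similarity_comparison(c("AAAAAAAAA", "KLMNPQRST"),
                                     c("AAAAAAAAA", "KLMNPQRST"), eps))
  expect_gte(res2$p, 0.9)

  # strictly separated groups match the exact permutation tail
  set.seed(5)
  aa <- rownames(blosum62())
  hi <- c("AAAAAAAAA", "AAAAAAAAC", "AAAAAAAAD")
  lo <- replicate(3, paste(sample(setdiff(aa, "A"), 9, TRUE), collapse = ""))
  epA <- data.frame(sequence = "AAAAAAAAA", assay_type = "T cell",
                    qualitative = "positive high", stringsAsFactors = FALSE)
  res3 <- iedb_similarity_comparison(hi, lo, epA)
  simhi <- vapply(hi, function(p) align_score(p, "AAAAAAAAA"), numeric(1))
  simlo <- vapply(lo, function(p) align_score(p, "AAAAAAAAA"), numeric(1))
  expect_equal(res3$p, brute_mww_p(simhi, simlo), tolerance = 1e-10)
  expect_identical(res3$direction, "high>low")
})
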
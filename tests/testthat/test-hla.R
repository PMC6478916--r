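# Consensus HLA typing and the homozygosity association test.

calls_df <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(caller = r[[1]], patient_id = r[[2]], locus = r[[3]],
               allele1 = r[[4]], allele2 = r[[5]], stringsAsFactors = FALSE)))
}

full_calls <- function(patient, a, b, c, caller = "POLYSOLVER") {
  calls_df(list(caller, patient, "HLA-A", a[1], a[2]),
           list(caller, patient, "HLA-B", b[1], b[2]),
           list(caller, patient, "HLA-C", c[1], c[2]))
}

test_that("consensus accepts order-free agreement from a recognised caller pair", {
  calls <- rbind(
    full_calls("P1", c("HLA-A*02:01", "HLA-A*01:01"),
               c("HLA-B*07:02", "HLA-B*08:01"),
               c("HLA-C*07:01", "HLA-C*04:01"), "POLYSOLVER"),
    full_calls("P1", c("HLA-A*01:01", "HLA-A*02:01"),  # swapped order
               c("HLA-B*08:01", "HLA-B*07:02"),
               c("HLA-C*04:01", "HLA-C*07:01"), "OptiType"))
  g <- consensus_type(calls, "P1")
  expect_true(g$complete)
  expect_length(g$alleles, 6L)
  expect_false(any(g$locus_homozygous))
})

test_that("PHLAT + seq2HLA agreement alone is not consensus", {
  calls <- rbind(
    full_calls("P1", c("HLA-A*02:01", "HLA-A*01:01"),
               c("HLA-B*07:02", "HLA-B*08:01"),
               c("HLA-C*07:01", "HLA-C*04:01"), "PHLAT"),
    full_calls("P1", c("HLA-A*02:01", "HLA-A*01:01"),
               c("HLA-B*07:02", "HLA-B*08:01"),
               c("HLA-C*07:01", "HLA-C*04:01"), "seq2HLA"))
  g <- consensus_type(calls, "P1")
  expect_false(g$complete)
  expect_true(all(is.na(g$locus_homozygous)))
})

test_that("homozygous loci are flagged and conflicting agreements give no consensus", {
  hom <- rbind(
    full_calls("P1", c("HLA-A*02:01", "HLA-A*02:01"),
               c("HLA-B*07:02", "HLA-B*08:01"),
               c("HLA-C*07:01", "HLA-C*04:01"), "POLYSOLVER"),
    full_calls("P1", c("HLA-A*02:01", "HLA-A*02:01"),
               c("HLA-B*07:02", "HLA-B*08:01"),
               c("HLA-C*07:01", "HLA-C*04:01"), "OptiType"))
  g <- consensus_type(hom, "P1")
  expect_true(g$locus_homozygous[["HLA-A"]])
  expect_true(any_homozygous(g))

  # POLYSOLVER+OptiType agree on one genotype, OptiType+PHLAT on another:
  # ambiguous, so no consensus at that locus
  conflict <- calls_df(
    list("POLYSOLVER", "P2", "HLA-A", "HLA-A*02:01", "HLA-A*02:01"),
    list("OptiType",   "P2", "HLA-A", "HLA-A*02:01", "HLA-A*02:01"),
    list("PHLAT",      "P2", "HLA-A", "HLA-A*01:01", "HLA-A*01:01"))
  conflict$allele1[2] <- "HLA-A*01:01"; conflict$allele2[2] <- "HLA-A*01:01"
  conflict2 <- calls_df(
    list("POLYSOLVER", "P2", "HLA-A", "HLA-A*02:01", "HLA-A*03:01"),
    list("OptiType",   "P2", "HLA-A", "HLA-A*02:01", "HLA-A*03:01"),
    list("PHLAT",      "P2", "HLA-A", "HLA-A*01:01", "HLA-A*01:01"),
    list("seq2HLA",    "P2", "HLA-A", "HLA-A*01:01", "HLA-A*01:01"))
  # here POLYSOLVER+OptiType and OptiType+... wait: OptiType+PHLAT disagree;
  # agreeing pairs: POLYSOLVER+OptiType -> 02:01/03:01 only, so consensus
  g2 <- consensus_type(conflict2, "P2")
  expect_identical(sort(g2$by_locus[["HLA-A"]]),
                   sort(c("HLA-A*02:01", "HLA-A*03:01")))

  expect_error(consensus_type(full_calls("P3", c("HLA-A*02:01", "HLA-A*01:01"),
                                         c("HLA-B*07:02", "HLA-B*08:01"),
                                         c("HLA-C*07:01", "HLA-C*04:01")),
                              "P3"),
               class = "insufficient_callers")
})

test_that("conflicting agreeing pairs at one locus yield no consensus", {
  calls <- calls_df(
    list("POLYSOLVER", "P1", "HLA-A", "HLA-A*02:01", "HLA-A*03:01"),
    list("OptiType",   "P1", "HLA-A", "HLA-A*02:01", "HLA-A*03:01"),
    list("PHLAT",      "P1", "HLA-A", "HLA-A*01:01", "HLA-A*24:02"),
    list("seq2HLA",    "P1", "HLA-A", "HLA-A*01:01", "HLA-A*24:02"))
  # add an OptiType row agreeing with PHLAT to create a genuine conflict
  calls$allele1[2] <- "HLA-A*01:01"; calls$allele2[2] <- "HLA-A*24:02"
  # now OptiType+PHLAT and OptiType+seq2HLA agree on 01:01/24:02 and no
  # pair supports 02:01/03:01 -> single genotype, accepted
  g <- consensus_type(calls, "P1")
  expect_identical(sort(g$by_locus[["HLA-A"]]),
                   sort(c("HLA-A*01:01", "HLA-A*24:02")))
})

test_that("homozygosity association reproduces the published one-sided Fisher p", {
  homo <- c(rep(TRUE, 53), rep(FALSE, 212 - 53),
            rep(TRUE, 6), rep(FALSE, 56 - 6))
  labels <- c(rep("low", 212), rep("high", 56))
  res <- homozygosity_association(homo, labels)
  expect_equal(res$p, 0.0136, tolerance = 0.0005 / 0.0136)
  expect_identical(unname(res$table[1, 1]), 53L + 0L)
})

test_that("Fisher p equals brute-force hypergeometric enumeration", {
  set.seed(42)
  for (rep in 1:10) {
    n_low <- sample(5:25, 1); n_high <- sample(5:25, 1)
    h_low <- rbinom(1, n_low, 0.4); h_high <- rbinom(1, n_high, 0.2)
    if (h_low == 0 && h_high == 0) next
    homo <- c(rep(TRUE, h_low), rep(FALSE, n_low - h_low),
              rep(TRUE, h_high), rep(FALSE, n_high - h_high))
    labels <- c(rep("low", n_low), rep("high", n_high))
    res <- homozygosity_association(homo, labels)
    expect_equal(res$p,
                 brute_fisher_greater(h_low, n_low - h_low,
                                      h_high, n_high - h_high),
                 tolerance = 1e-10)
  }
  # identical proportions cannot show enrichment
  res <- homozygosity_association(c(TRUE, FALSE, TRUE, FALSE),
                                  c("low", "low", "high", "high"))
  expect_gte(res$p, 0.5)
  expect_error(homozygosity_association(c(TRUE, FALSE), c("low", "low")),
               "empty")
})
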
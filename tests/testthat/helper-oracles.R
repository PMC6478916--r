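# Independent brute-force oracles used to validate the analytical
# implementations on small instances.

# Gapless alignment: exhaustive enumeration of all offsets.
brute_align <- function(peptide, epitope, mat) {
  w <- nchar(peptide)
  if (nchar(epitope) < w) return(NA_integer_)
  p <- strsplit(peptide, "")[[1]]
  e <- strsplit(epitope, "")[[1]]
  best <- -Inf
  for (s in 1:(length(e) - w + 1)) {
    sc <- 0
    for (j in 1:w) sc <- sc + mat[p[j], e[s + j - 1]]
    best <- max(best, sc)
  }
  best
}

# Mann-Whitney U for group x against y by direct pair counting
# (mid-tie pairs count 1/2).
brute_mww_u <- function(x, y) {
  u <- 0
  for (xi in x) for (yi in y) {
    u <- u + (xi > yi) + 0.5 * (xi == yi)
  }
  u
}

# Exact two-sided MWW p by enumerating all assignments of the pooled
# values to the two groups.
brute_mww_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  combos <- utils::combn(length(pooled), n)
  obs <- brute_mww_u(x, y)
  mu <- length(x) * length(y) / 2
  us <- apply(combos, 2, function(idx)
    brute_mww_u(pooled[idx], pooled[-idx]))
  mean(abs(us - mu) >= abs(obs - mu) - 1e-12)
}

# One-sided Fisher p (greater) by hypergeometric tail enumeration over all
# tables with the observed margins.
brute_fisher_greater <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- vapply(lo:hi, function(x)
    choose(m, x) * choose(n, k - x) / choose(m + n, k), numeric(1))
  sum(probs[(lo:hi) >= a])
}

# Product-limit estimator by direct evaluation.
brute_km <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  surv <- numeric(length(ut))
  s <- 1
  for (i in seq_along(ut)) {
    n_risk <- sum(time >= ut[i])
    d <- sum(time == ut[i] & event == 1)
    s <- s * (1 - d / n_risk)
    surv[i] <- s
  }
  data.frame(time = ut, survival = surv)
}

# Two-group Mantel-Cox chi-square from explicit per-event-time risk
# tables.
brute_logrank <- function(time, event, group) {
  g <- as.integer(factor(group))
  ut <- sort(unique(time[event == 1]))
  O1 <- 0; E1 <- 0; V <- 0
  for (t in ut) {
    n1 <- sum(time >= t & g == 1); n2 <- sum(time >= t & g == 2)
    N <- n1 + n2
    d1 <- sum(time == t & event == 1 & g == 1)
    d <- sum(time == t & event == 1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / N
    if (N > 1) V <- V + d * (n1 / N) * (n2 / N) * (N - d) / (N - 1)
  }
  (O1 - E1)^2 / V
}

# MWW-GST NES via its probability interpretation: the fraction of
# (in-set, out-set) pairs where the in-set gene ranks higher (ties 1/2).
brute_nes <- function(values, gene_set) {
  inset <- names(values) %in% gene_set
  brute_mww_u(values[inset], values[!inset]) /
    (sum(inset) * sum(!inset))
}

# Small deterministic toy fixtures -----------------------------------

toy_mutation <- function(patient = "P1", gene = "EGFR",
                         context = "MKLVNAPQRSTWYFHCDEGI", position = 10,
                         alt = "W") {
  data.frame(patient_id = patient, gene = gene, protein_context = context,
             position = position, ref = substr(context, position, position),
             alt = alt, stringsAsFactors = FALSE)
}

toy_affinities <- function(rows) {
  affinity_lookup(do.call(rbind, lapply(rows, function(r)
    data.frame(peptide = r[[1]], allele = r[[2]],
               ic50_nM = as.numeric(r[[3]]), stringsAsFactors = FALSE))))
}
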
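# neoquality

Neoantigen quality modelling and immune survival stratification for tumor
cohorts.

## The problem

In most solid tumors a higher mutational burden means more predicted
neoantigens and better response to immunotherapy. Glioblastoma behaves
differently: neoantigen *count* tracks mutation load and fails to separate
survivors. The quality-model view is that what matters is a small set of
*high-quality* neoantigens — mutant 9-mer peptides that bind the patient's
HLA class I molecules while their wild-type counterparts do not, and that
resemble pathogen-derived epitopes the T-cell repertoire already
recognises. `neoquality` implements this model for cohort analysis:

* **Neoantigen calling.** All 9-mer windows over each missense mutation;
  a (peptide, allele) pair is a neoantigen iff the mutant IC50 is below
  500 nM on the restricted allele *and* the wild-type IC50 exceeds 500 nM
  on **all** of the patient's alleles. HLA genotypes are the consensus of
  four callers at four-digit resolution.
* **Fitness scoring.** Each neoantigen gets a recognition potential
  NRP = A x R, with amplitude
  A = (Kd_WT / Kd_MT) / (1 + (eps/[L]) Kd_WT) (eps/[L] = 3e-4) and
  recognition R = 1 / (1 + exp(-k (s* - a))), where s* is the best gapless
  BLOSUM62 alignment of the mutant peptide against an epitope database.
  Patient quality is the mean NRP; cohorts split at the mean.
* **Training and validation.** (a, k) are trained by maximising the
  two-group log-rank chi-square over a grid (default 40 x 100 = 4000
  settings), with leave-one-out cross validation, 4:1 random-subsampling
  validation and permutation p-values.
* **Stratification.** Quality labels intersect with immune-cell
  enrichment labels (per-sample MWW-GST NES, median split) into four
  groups; the headline comparison is high-quality/high-CD8 versus
  low-quality/low-CD8, plus Cox models adjusted for age, gender and
  mutation load.
* **Downstream.** ee-MWW ranked differential statistics, GO-style NES
  enrichment with overlap-coefficient enrichment maps, edgeR/Wilcoxon
  differential expression, differential methylation, starburst
  integration, Fisher-exact GO analysis, and the alteration-landscape
  gene selection.
* **Synthetic cohorts.** A seeded generator produces complete cohorts
  (mutations, affinities, HLA caller tables, labelled epitopes, clinical,
  expression, methylation, ground truth) so every stage runs and is
  validated without external data.

## Worked example

```r
library(neoquality)

co <- simulate_cohort(cohort_config(seed = 42))   # 120 patients
pl <- cohort_pipeline(co, grid = nq_grid(a_values = c(13, 17, 21, 25, 29),
                                         k_values = c(0.4, 0.8, 1.6, 3.2)))
print(pl$fit)
#> Neoantigen quality model fit
#>   a = 17, k = 3.2 (grid of 20 settings)
#>   log-rank chi-square = 5.176, p = 0.0229
#>   groups: 55 high / 65 low quality (mean threshold 6.653)

table(pl$four_group$labels)
#> Q+I+ Q+I- Q-I+ Q-I-
#>   26   29   34   31
signif(pl$four_group$headline$p, 3)   # Q+I+ vs Q-I- log-rank
#> [1] 0.000121
```

The fit says the trained sigmoid (a = 17, k = 3.2) splits this cohort into
55 high- and 65 low-quality patients whose survival differs at p = 0.023;
combining quality with CD8 T-cell enrichment isolates 26 patients whose
survival advantage over the 31 double-negative patients is much stronger
(p = 1.2e-4) — the synergy the model is designed to expose. Against the
generator's ground truth the quality labels agree at 98% here
(`oracle_report(co, ...)`).

The homozygosity association test reproduces a published cohort statistic
directly from its printed counts:

```r
res <- homozygosity_association(
  c(rep(TRUE, 53), rep(FALSE, 159), rep(TRUE, 6), rep(FALSE, 50)),
  c(rep("low", 212), rep("high", 56)))
signif(res$p, 3)
#> [1] 0.0136
```

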
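# Kaplan-Meier / log-rank machinery, Cox multivariate models and the
# quality x immune-infiltration four-group stratification.

# Fast k-group Mantel-Cox chi-square used inside grid search, LOOCV and the
# permutation loops (orders of magnitude cheaper than building survdiff
# objects); cross-checked against survival::survdiff in the test suite.
logrank_chisq <- function(time, event, group) {
  ug <- unique(group)
  if (length(ug) == 2L) return(logrank2_chisq(time, event, group == ug[1]))
  g <- match(group, ug)
  k <- length(ug)
  if (k < 2L) return(NA_real_)
  o <- order(time)
  time <- time[o]; event <- event[o]; g <- g[o]
  n <- length(time)
  # at-risk counts per group just before each event time
  ut <- unique(time[event == 1L])
  if (length(ut) == 0L) return(NA_real_)
  O <- numeric(k); E <- numeric(k)
  V <- matrix(0, k, k)
  for (t in ut) {
    at <- time >= t
    nj <- tabulate(g[at], nbins = k)
    N <- sum(nj)
    dj <- tabulate(g[time == t & event == 1L], nbins = k)
    d <- sum(dj)
    if (N <= 1L) next
    O <- O + dj
    E <- E + d * nj / N
    cf <- d * (N - d) / (N - 1)
    V <- V + cf * (diag(nj / N, k, k) - outer(nj, nj) / N^2)
  }
  idx <- seq_len(k - 1L)
  v <- V[idx, idx, drop = FALSE]
  dlt <- (O - E)[idx]
  if (all(abs(v) < 1e-300)) return(NA_real_)
  if (qr(v)$rank < length(idx))
    return(drop(t(dlt) %*% MASS::ginv(v) %*% dlt))
  drop(t(dlt) %*% solve(v, dlt))
}

# Vectorised two-group Mantel-Cox chi-square (g1 logical: membership of
# group 1); O(n log n), no per-event-time loop.
logrank2_chisq <- function(time, event, g1) {
  o <- order(time)
  t_s <- time[o]; e_s <- event[o]; g_s <- g1[o]
  n <- length(t_s)
  first <- !duplicated(t_s)
  idx <- which(first)
  nrisk <- n - idx + 1L
  n1risk <- sum(g_s) - c(0, cumsum(g_s))[idx]
  d <- rowsum(e_s, t_s, reorder = FALSE)[, 1]
  d1 <- rowsum(e_s * g_s, t_s, reorder = FALSE)[, 1]
  keep <- d > 0
  if (!any(keep)) return(NA_real_)
  d <- d[keep]; d1 <- d1[keep]
  nrisk <- nrisk[keep]; n1risk <- n1risk[keep]
  p1 <- n1risk / nrisk
  O1 <- sum(d1)
  E1 <- sum(d * p1)
  ok <- nrisk > 1
  V <- sum((d * p1 * (1 - p1) * (nrisk - d) / (nrisk - 1))[ok])
  if (V <= 0) return(NA_real_)
  (O1 - E1)^2 / V
}

#' Kaplan-Meier curves and Mantel-Cox log-rank test
#'
#' @param time Survival times.
#' @param event Event indicators (1 = event, 0 = censored).
#' @param labels Group labels (>= 2 groups, each non-empty).
#' @return List with `chisq`, `df`, `p`, and `km` — a named list of
#'   per-group product-limit tables (time, n_risk, n_event, survival).
#' @export
km_logrank <- function(time, event, labels) {
  f <- factor(labels)
  if (nlevels(f) < 2L) stopf("log-rank needs at least two groups")
  if (any(table(f) == 0L)) stopf("a group has zero subjects")
  if (sum(event) < 1L) stopf("log-rank needs at least one event")
  sd <- survival::survdiff(survival::Surv(time, event) ~ f)
  df <- length(sd$n) - 1L
  fit <- survival::survfit(survival::Surv(time, event) ~ f)
  strata <- rep(names(fit$strata), fit$strata)
  km <- lapply(levels(f), function(lv) {
    sel <- strata == paste0("f=", lv)
    data.frame(time = fit$time[sel], n_risk = fit$n.risk[sel],
               n_event = fit$n.event[sel], survival = fit$surv[sel])
  })
  names(km) <- levels(f)
  list(chisq = sd$chisq, df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE), km = km)
}

#' Four-group stratification by neoantigen quality and immune enrichment
#'
#' Intersects the quality labels (mean split) with the immune-signature NES
#' labels (median split) into Q+I+, Q+I-, Q-I+, Q-I-. The headline
#' comparison is the log-rank between Q+I+ (high quality, high
#' infiltration) and Q-I-; the omnibus test over all four groups is also
#' reported.
#'
#' @param quality_labels `"high"`/`"low"` per patient.
#' @param nes_labels `"high"`/`"low"` per patient (same order).
#' @param time,event Survival data (same order).
#' @return List with `labels` (four-group factor), `headline` (Q+I+ vs Q-I-
#'   log-rank, or `NULL` with a `skipped` message when a corner group is
#'   empty), and `omnibus` (all-group log-rank when >= 2 groups are
#'   non-empty).
#' @export
four_group_stratify <- function(quality_labels, nes_labels, time, event) {
  stopifnot(length(quality_labels) == length(nes_labels))
  lab <- paste0(ifelse(quality_labels == "high", "Q+", "Q-"),
                ifelse(nes_labels == "high", "I+", "I-"))
  lab <- factor(lab, levels = c("Q+I+", "Q+I-", "Q-I+", "Q-I-"))
  out <- list(labels = lab)
  corner <- lab %in% c("Q+I+", "Q-I-")
  if (!any(lab == "Q+I+") || !any(lab == "Q-I-")) {
    out$headline <- NULL
    out$skipped <- "headline comparison skipped: an extreme group is empty"
  } else {
    out$headline <- km_logrank(time[corner], event[corner],
                               droplevels(lab[corner]))
  }
  present <- droplevels(lab)
  out$omnibus <- if (nlevels(present) >= 2L)
    km_logrank(time, event, present) else NULL
  out
}

#' Multivariate Cox proportional-hazards model
#'
#' Fits survival against a group indicator adjusted for clinical covariates
#' (Efron tie handling), reporting hazard ratios with Wald p-values.
#'
#' @param time,event Survival data.
#' @param covariates Data frame of covariates (e.g. group, age, gender,
#'   mutation_load); constant columns are an error.
#' @return Data frame (term, hr, se_loghr, z, p, ci_low, ci_high), or an
#'   error condition described as non-estimable on separation /
#'   non-convergence.
#' @export
cox_multivariate <- function(time, event, covariates) {
  covariates <- as.data.frame(covariates)
  for (nm in names(covariates)) {
    v <- covariates[[nm]]
    if (length(unique(v[!is.na(v)])) < 2L)
      stopf("constant covariate '%s': model non-estimable", nm)
  }
  dat <- cbind(data.frame(.time = time, .event = event), covariates)
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                 paste(names(covariates), collapse = " + ")))
  fit <- tryCatch(
    survival::coxph(fml, data = dat, ties = "efron"),
    error = function(e) stopf("Cox model non-estimable: %s", conditionMessage(e)),
    warning = function(w) {
      suppressWarnings(survival::coxph(fml, data = dat, ties = "efron"))
    })
  s <- summary(fit)
  co <- s$coefficients
  data.frame(term = rownames(co),
             hr = co[, "exp(coef)"],
             se_loghr = co[, "se(coef)"],
             z = co[, "z"],
             p = co[, "Pr(>|z|)"],
             ci_low = s$conf.int[, "lower .95"],
             ci_high = s$conf.int[, "upper .95"],
             row.names = NULL, stringsAsFactors = FALSE)
}
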
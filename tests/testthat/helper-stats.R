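# Independent statistics oracles and small model fixtures.

# Log-rank statistic from first principles (O-E)^2/V over distinct
# event times; independent of survival::survdiff.
logrank_stat_manual <- function(times, events, group) {
  ev_times <- sort(unique(times[events == 1]))
  O <- E <- V <- 0
  for (t in ev_times) {
    at_risk <- times >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & group)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# Permutation reference for the log-rank p-value.
perm_logrank_p <- function(times, events, group, B = 4000, seed = 99) {
  set.seed(seed)
  obs <- logrank_stat_manual(times, events, group)
  hits <- 0
  for (b in seq_len(B)) {
    g <- sample(group)
    if (logrank_stat_manual(times, events, g) >= obs) hits <- hits + 1
  }
  hits / B
}

# Brute-force Mann-Whitney AUC by pair counting (ties = 1/2).
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# A hand-built diploid tumor model covering chr1:1-10e6.
toy_model <- function(P = 0.5, C = 2L, M = 1L, psi = 2) {
  segs <- data.frame(chrom = "chr1", start = 1L, end = 10000000L, n_bins = 100L,
                     observed_logratio = tmbforge::expected_logratio(P, C, psi),
                     C = C, M = M,
                     expected_logratio = tmbforge::expected_logratio(P, C, psi),
                     stringsAsFactors = FALSE)
  structure(list(purity = P, ploidy = psi, segments = segs, fit_score = 0,
                 identifiable = TRUE), class = "tumor_model")
}
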
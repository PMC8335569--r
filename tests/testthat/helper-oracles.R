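# Independent oracles used to check the package's implementations.
# These are deliberately naive (loops, direct formulas) and share no code
# with the implementation paths they verify.

# literal running-sum ssGSEA: for one sample vector x (named by gene),
# walk positions i = 1..N of the descending-expression order (ties by
# ascending gene id) and accumulate P_hit - P_miss.
oracle_ssgsea_sample <- function(x, set, alpha) {
  genes <- names(x)
  ord <- order(-x, genes)          # descending value, ties by ascending id
  N <- length(x)
  in_set <- genes[ord] %in% set
  rankvalue <- (N - seq_len(N) + 1)^alpha
  denom_hit <- sum(rankvalue[in_set])
  es <- 0
  hits <- 0; misses <- 0; whit <- 0
  for (i in seq_len(N)) {
    if (in_set[i]) whit <- whit + rankvalue[i] else misses <- misses + 1
    p_hit <- whit / denom_hit
    p_miss <- misses / (N - sum(in_set))
    es <- es + (p_hit - p_miss)
  }
  es
}

# two-sided Fisher p by explicit enumeration of margin-fixed tables, with
# probabilities from the factorial formula
oracle_fisher_p <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c; n <- m1 + m2
  if (m1 == 0 || m2 == 0 || k == 0 || (b + d) == 0) return(1)
  xs <- max(0, k - m2):min(k, m1)
  lp <- lfactorial(m1) + lfactorial(m2) + lfactorial(k) + lfactorial(n - k) -
    lfactorial(n) - lfactorial(xs) - lfactorial(m1 - xs) -
    lfactorial(k - xs) - lfactorial(m2 - k + xs)
  probs <- exp(lp)
  pobs <- probs[xs == a]
  min(1, sum(probs[probs <= pobs * (1 + 1e-7)]))
}

# BH step-up by direct definition: q(i) = min over j >= i of p(j) * m / j
# on the ascending-sorted p, mapped back to input order
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  qs <- vapply(seq_len(m), function(i) min(1, min(ps[i:m] * m / (i:m))), 0)
  out <- numeric(m)
  out[o] <- qs
  out
}

# two-group log-rank chi-square from the at-risk table, summed over distinct
# event times
oracle_logrank_chisq <- function(time, event, group) {
  g1 <- levels(factor(group))[1]
  ts <- sort(unique(time[event == 1]))
  OE <- 0; V <- 0
  for (t in ts) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    OE <- OE + d1 - d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  OE^2 / V
}

# the s0 selection criterion (CV of windowed MADs of d), recomputed from its
# definition for an exhaustive candidate scan
oracle_s0_cv <- function(diff, s, s0, n_windows) {
  d <- diff / (s + s0)
  win <- as.integer(cut(rank(s, ties.method = "first"),
                        breaks = n_windows, labels = FALSE))
  mads <- tapply(d, win, mad)
  sd(mads) / mean(mads)
}

# pooled scatter and mean difference per row, by direct per-class formulas
oracle_sam_parts <- function(x, lab) {
  x1 <- x[lab == 1]; x0 <- x[lab == 0]
  n1 <- length(x1); n0 <- length(x0)
  s <- sqrt((1 / n1 + 1 / n0) / (n1 + n0 - 2) *
              (sum((x1 - mean(x1))^2) + sum((x0 - mean(x0))^2)))
  list(diff = mean(x1) - mean(x0), s = s)
}
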
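# Independent brute-force oracles used to pin down expected values.

# Exhaustive scan of every contiguous window: longest window with at most
# max_below bases under the floor, leftmost on ties.
oracle_best_window <- function(phred, floor, max_below) {
  n <- length(phred)
  best <- NULL
  best_len <- 0L
  for (i in seq_len(n)) for (j in i:n) {
    if (sum(phred[i:j] < floor) <= max_below && (j - i + 1L) > best_len) {
      best <- c(i, j)
      best_len <- j - i + 1L
    }
  }
  best
}

# Exact two-sided Fisher p by direct enumeration of all tables with the
# observed margins, probabilities computed from products of choose().
oracle_fisher <- function(a, b, c, d) {
  m <- a + c; n <- b + d; k <- a + b
  if (m == 0 || n == 0 || k == 0 || (c + d) == 0) return(1)
  support <- max(0, k - n):min(k, m)
  probs <- choose(m, support) * choose(n, k - support) / choose(m + n, k)
  p_obs <- choose(m, a) * choose(n, k - a) / choose(m + n, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-12)]))
}

# Manual Benjamini-Hochberg step-up.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- p[ord] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  out <- numeric(m)
  out[ord] <- q_sorted
  out
}

# ANOSIM R computed straight from the definition for a given labelling.
oracle_anosim_r <- function(d, groups) {
  lower <- lower.tri(d)
  rnk <- rank(d[lower])
  same <- outer(groups, groups, "==")[lower]
  m <- length(rnk)
  (mean(rnk[!same]) - mean(rnk[same])) / (m / 2)
}
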
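# Independent brute-force oracles used to check the analytical / DP paths.

# Ansari-Bradley one-sided p by exhaustive enumeration of group assignments,
# recomputing midranks and scores from scratch for the combined sample.
ab_enumeration_oracle <- function(x, y) {
  z <- c(x, y)
  N <- length(z)
  n1 <- length(x)
  r <- rank(z)
  score <- pmin(r, N + 1 - r)
  obs <- sum(score[seq_len(n1)])
  assignments <- utils::combn(N, n1)
  sums <- apply(assignments, 2, function(idx) sum(score[idx]))
  mean(sums <= obs + 1e-9)
}

# Poisson-binomial tail by explicit enumeration of all 2^n outcomes.
pb_enumeration_oracle <- function(probs, k, tail) {
  n <- length(probs)
  outcomes <- as.matrix(expand.grid(rep(list(0:1), n)))
  pr <- apply(outcomes, 1, function(o) prod(ifelse(o == 1, probs, 1 - probs)))
  cnt <- rowSums(outcomes)
  if (tail == "lower") sum(pr[cnt <= k]) else sum(pr[cnt >= k])
}

# Tangent cutoff by an O(n^2) count-of-points-below-line scan: for each
# candidate point, count points strictly below the unit-slope line through
# it; tangent candidates have zero points below; ties resolve upward.
rose_scan_oracle <- function(signals) {
  s <- sort(signals)
  n <- length(s)
  x <- (seq_len(n) - 1) / (n - 1)
  y <- (s - s[1]) / (s[n] - s[1])
  below <- vapply(seq_len(n), function(i) {
    sum(y < y[i] + (x - x[i]) - 1e-12)
  }, numeric(1))
  cand <- which(below == 0)
  s[max(cand)]
}

# Jaccard overlap of two sets
jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
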
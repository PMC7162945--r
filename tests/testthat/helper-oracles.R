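# Independent oracles used by the tests; deliberately brute-force and kept
# free of any package internals.

# adjusted Rand index between two labelings (vectors of equal length)
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(length(a), 2)
  expected <- ai * bj / n2
  (nij - expected) / ((ai + bj) / 2 - expected)
}

# hypergeometric upper tail by direct combinatorial summation
hyper_upper_oracle <- function(k, n, K, N) {
  j <- k:min(n, K)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# hypergeometric lower tail by direct summation
hyper_lower_oracle <- function(k, n, K, N) {
  j <- max(0, n - (N - K)):k
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Kendall-type S for a single pair of vectors, written independently
s_stat_oracle <- function(x, r) {
  s <- 0
  n <- length(x)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      s <- s + sign(x[j] - x[i]) * sign(r[j] - r[i])
    }
  }
  s
}

# a small synthetic two-organ dataset reused by pipeline tests
make_small_dataset <- function(seed = 11, n = 300) {
  d <- diel_design()
  spec <- list(n_transcripts = n, rhythmic_fraction = 0.3,
               amplitude_range = c(1, 1), noise_sd = 0.25,
               dropout_rate = 0.1, n_replicates = 2)
  simulate_multi_organ(d, list(L1 = spec, I1 = spec),
                       sharing_spec(round(0.75 * n), round(0.15 * n)),
                       seed = seed)
}
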
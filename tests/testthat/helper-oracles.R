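# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: the DFT oracle is an O(n^2) matrix product, the
# Wilcoxon oracle enumerates all 2^m sign assignments explicitly.

# Brick-wall bandpass via an explicit DFT matrix (O(n^2); small n only).
oracle_dft_bandpass <- function(x, fs, f_lo, f_hi, edge_inclusive = TRUE) {
  n <- length(x)
  k <- 0:(n - 1)
  W <- exp(-2i * pi * outer(k, k) / n)
  X <- as.vector(W %*% x)
  freq <- pmin(k, n - k) * fs / n
  keep <- if (edge_inclusive) freq >= f_lo & freq <= f_hi
  else freq > f_lo & freq < f_hi
  X[!keep] <- 0
  Re(as.vector(Conj(W) %*% X) / n)
}

# Exact Wilcoxon signed-rank p by explicit enumeration of sign patterns.
# Mirrors the classical definitions: drop (or Pratt) zero handling,
# mid-ranks for ties, W = sum of positive-difference ranks.
oracle_wilcoxon <- function(d, alternative = "two_sided",
                            zero_policy = "drop") {
  if (zero_policy == "drop") {
    d <- d[d != 0]
    if (length(d) == 0) return(list(W = 0, p = 1))
    r <- rank(abs(d))
    active <- r
  } else {
    r <- rank(abs(d))
    active <- r[d != 0]
    if (length(active) == 0) return(list(W = 0, p = 1))
  }
  W <- sum(r[d > 0])
  m <- length(active)
  sums <- vapply(0:(2^m - 1), function(mask) {
    signs <- bitwAnd(bitwShiftR(mask, 0:(m - 1)), 1L) == 1L
    sum(active[signs])
  }, numeric(1))
  p_ge <- mean(sums >= W - 1e-12)
  p_le <- mean(sums <= W + 1e-12)
  p <- switch(alternative,
              two_sided = min(1, 2 * min(p_ge, p_le)),
              greater = p_ge,
              less = p_le)
  list(W = W, p = p)
}

# Per-block RMS by an explicit scalar loop.
oracle_block_rms <- function(x, block) {
  nw <- length(x) %/% block
  out <- numeric(nw)
  for (i in seq_len(nw)) {
    acc <- 0
    for (j in seq_len(block)) acc <- acc + x[(i - 1) * block + j]^2
    out[i] <- sqrt(acc / block)
  }
  out
}

# Small fast simulator configuration for pipeline-level tests.
quick_sim <- function(n_subjects = 3, seed = 1, include = "both",
                      post_reversal_s = 960, ...) {
  sim_config(n_subjects = n_subjects, include = include,
             level_duration_s = 120, pre_reversal_s = 120,
             post_reversal_s = post_reversal_s, seed = seed, ...)
}
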
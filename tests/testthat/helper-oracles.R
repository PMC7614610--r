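# Independent oracles used across the suite. These re-derive expected
# results by direct enumeration or literal transcription of the level
# formulas, without calling the package's procedure code paths.

# Step-up search: largest k such that the k-th smallest p-value is below
# k*q/M; rejects everything at or below that threshold.
bh_bruteforce <- function(p, q) {
  M <- length(p)
  if (M == 0) return(logical(0))
  ps <- sort(p)
  ok <- which(ps <= seq_len(M) * q / M)
  if (length(ok) == 0) return(rep(FALSE, M))
  k <- max(ok)
  p <= ps[k]
}

# Hand-stepped SAFFRON level recursion: explicit candidate counting per
# discovery epoch, gamma indexed with out-of-range lags treated as zero.
saffron_oracle <- function(p, alpha, gamma, lambda, W0) {
  g <- function(j) if (j >= 1 && j <= length(gamma)) gamma[j] else 0
  m <- length(p)
  lev <- numeric(m)
  rej <- logical(m)
  for (i in seq_len(m)) {
    cand_pos <- which(p[seq_len(i - 1)] <= lambda)
    taus <- which(rej[seq_len(i - 1)])
    val <- W0 * g(i - length(cand_pos))
    for (j in seq_along(taus)) {
      cj <- sum(cand_pos > taus[j])
      budget <- if (j == 1) (1 - lambda) * alpha - W0 else (1 - lambda) * alpha
      val <- val + budget * g(i - taus[j] - cj)
    }
    lev[i] <- min(lambda, val)
    rej[i] <- p[i] <= lev[i]
  }
  list(alphai = lev, rejected = rej)
}

# Random streams for property tests: mixture of uniforms and strong
# signals so rejection paths actually branch.
random_stream <- function(m = 12, signal_frac = 0.3) {
  p <- stats::runif(m)
  hot <- stats::runif(m) < signal_frac
  p[hot] <- stats::rbeta(sum(hot), 0.15, 8)
  p
}
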
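# Independent brute-force oracles. These deliberately avoid the package's
# computation paths: everything is enumerated from the collapsed joint.

# P(b_z | c, pi, gamma) by enumerating all 2^m expression vectors z
# consistent with c (z_j = 1 forced where c_j > 0) under the collapsed
# weight pi^b (1-pi)^(m-b) * Gamma(b g)/Gamma(n + b g) *
# prod_{j expressed} Gamma(c_j + g)/Gamma(g), then tallying by b.
oracle_bz_distribution <- function(c_counts, pi, gamma) {
  m <- length(c_counts)
  n <- sum(c_counts)
  w_by_b <- numeric(m + 1L)  # index b + 1
  for (code in 0:(2^m - 1L)) {
    z <- as.integer(intToBits(code)[1:m])
    if (any(c_counts > 0L & z == 0L)) next
    b <- sum(z)
    if (b == 0L) next  # zero-truncated prior
    w <- pi^b * (1 - pi)^(m - b) *
      exp(lgamma(b * gamma) - lgamma(n + b * gamma)) *
      prod(exp(lgamma(c_counts[z == 1L] + gamma) - lgamma(gamma)))
    w_by_b[b + 1L] <- w_by_b[b + 1L] + w
  }
  supp <- which(w_by_b > 0) - 1L
  p <- w_by_b[supp + 1L] / sum(w_by_b)
  setNames(p, supp)
}

# Monte-Carlo standard error by batch means (accounts for autocorrelation).
batch_se <- function(x, n_batches = 50L) {
  nb <- min(n_batches, length(x) %/% 2L)
  bs <- length(x) %/% nb
  means <- vapply(seq_len(nb), function(k)
    mean(x[((k - 1L) * bs + 1L):(k * bs)]), numeric(1L))
  stats::sd(means) / sqrt(nb)
}
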
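# Independent brute-force oracles used to freeze expected values.

# Two-sided Fisher exact p by full enumeration over all 2x2 tables with the
# observed margins: sum of hypergeometric probabilities not exceeding the
# observed table's probability (relative tie tolerance guards the
# floating-point comparison of equal-probability tables).
fisher_oracle_two_sided <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  x <- max(0, k - n):min(k, m)
  probs <- dhyper(x, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# One-sided (upper tail in cell a) Fisher exact p.
fisher_oracle_greater <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  x <- a:min(k, m)
  sum(dhyper(x, m, n, k))
}

fisher_oracle_less <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  x <- max(0, k - n):a
  sum(dhyper(x, m, n, k))
}

# Exact one-sided signed-rank p by enumerating all 2^n sign assignments.
signed_rank_oracle <- function(x, mu, alternative = "greater") {
  d <- x - mu
  d <- d[d != 0]
  if (alternative == "less") d <- -d
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  w_all <- apply(signs, 1, function(s) sum(r[s]))
  mean(w_all >= w_obs - 1e-9)
}

# Exact one-sided rank-sum p by enumerating all choose(m+n, m) group
# assignments.
rank_sum_oracle <- function(x, y, alternative = "less") {
  m <- length(x)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(m)])
  idx <- utils::combn(length(r), m)
  w_all <- apply(idx, 2, function(i) sum(r[i]))
  if (alternative == "less") mean(w_all <= w_obs + 1e-9)
  else mean(w_all >= w_obs - 1e-9)
}

# Brute-force per-bp mean copy number of a segment set over an interval
# (0-based half-open), uncovered bp counted at `fill` (NA = ignore).
per_bp_mean_cn <- function(segments, chrom, start, end, fill = NA) {
  cn <- rep(fill, end - start)
  for (i in seq_len(nrow(segments))) {
    if (segments$chrom[i] != chrom) next
    lo <- max(start, segments$start[i]); hi <- min(end, segments$end[i])
    if (lo < hi) cn[(lo - start + 1):(hi - start)] <- segments$copy_number[i]
  }
  mean(cn, na.rm = is.na(fill))
}
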
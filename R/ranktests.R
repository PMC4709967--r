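#' Exact and approximate rank tests with tied data
#'
#' One-sample Wilcoxon signed-rank and two-sample Wilcoxon/Mann-Whitney
#' rank-sum tests used by the somatic SNV read-evidence criteria and the
#' copy-number burden comparison. Unlike [stats::wilcox.test()], the exact
#' conditional null distribution is computed even in the presence of ties
#' (and, for the signed-rank test, of zero differences, which are dropped),
#' via a generating-function convolution over doubled midranks. Beyond the
#' exact-size cutoffs a normal approximation with tie correction and
#' continuity correction is used.
#'
#' @name ranktests
#' @keywords internal
NULL

# Distribution of the sum of "selected" values under the signed-rank null:
# each doubled midrank independently included with probability 1/2.
# Returns P(W2 >= w2) where W2 is the doubled positive-rank sum.
.signed_rank_exact_tail <- function(r2, w2) {
  total <- sum(r2)
  f <- numeric(total + 1L) # f[s+1] = #assignments with doubled sum s
  f[1L] <- 1
  for (r in r2) {
    g <- f
    idx <- seq_len(total + 1L - r)
    g[idx + r] <- g[idx + r] + f[idx]
    f <- g
  }
  sum(f[(w2 + 1L):(total + 1L)]) / 2^length(r2)
}

#' One-sample Wilcoxon signed-rank test against a reference value
#'
#' Tests whether the values in `x` are located above (or below) `mu`.
#' Differences equal to zero are dropped; absolute differences are ranked
#' with midranks. For `n <= exact_limit` informative observations the exact
#' conditional null (given the tie pattern) is evaluated by dynamic
#' programming; otherwise a tie-corrected normal approximation with
#' continuity correction is used.
#'
#' @param x numeric vector of observations.
#' @param mu reference value under the null.
#' @param alternative `"greater"` (default) or `"less"`.
#' @param exact_limit largest number of non-zero differences for which the
#'   exact null is enumerated (default 25).
#' @return list with `statistic` (positive-rank sum W+), `n` (informative
#'   observations), `p.value`, and `exact` flag. If all differences are zero
#'   the test is uninformative and `p.value` is 1.
#' @examples
#' signed_rank_test(c(60, 60, 60), mu = 30)$p.value # 1/8
#' @export
signed_rank_test <- function(x, mu,
                             alternative = c("greater", "less"),
                             exact_limit = 25L) {
  alternative <- match.arg(alternative)
  stopifnot(is.numeric(x), length(x) >= 1L, is.finite(mu))
  d <- x - mu
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(list(statistic = NA_real_, n = 0L, p.value = 1, exact = TRUE))
  }
  if (alternative == "less") d <- -d
  r <- rank(abs(d)) # midranks
  w <- sum(r[d > 0])
  if (n <= exact_limit) {
    r2 <- as.integer(round(2 * r))
    p <- .signed_rank_exact_tail(r2, as.integer(round(2 * w)))
    return(list(statistic = w, n = n, p.value = p, exact = TRUE))
  }
  ew <- n * (n + 1) / 4
  tie_tab <- table(r)
  vw <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
  z <- (w - ew - 0.5) / sqrt(vw)
  list(statistic = w, n = n,
       p.value = stats::pnorm(z, lower.tail = FALSE), exact = FALSE)
}

# Exact tail of the rank-sum of m values drawn without replacement from the
# doubled midranks r2 (length N). Returns the full distribution as a list
# (sums are doubled). DP over items tracking (#chosen, doubled sum).
.rank_sum_exact_dist <- function(r2, m) {
  total <- sum(r2)
  # f[[k+1]][s+1] = #subsets of size k with doubled sum s
  f <- matrix(0, nrow = m + 1L, ncol = total + 1L)
  f[1L, 1L] <- 1
  for (r in r2) {
    kmax <- m
    for (k in kmax:1L) {
      idx <- seq_len(total + 1L - r)
      f[k + 1L, idx + r] <- f[k + 1L, idx + r] + f[k, idx]
    }
  }
  f[m + 1L, ]
}

#' Two-sample Wilcoxon/Mann-Whitney rank-sum test
#'
#' Tests whether values in `x` tend to be smaller (`alternative = "less"`)
#' or larger (`"greater"`) than values in `y`. Midranks are used for ties.
#' When both groups have at most `exact_limit` observations the exact
#' conditional null (given the observed tie pattern) is computed by dynamic
#' programming over all `choose(m+n, m)` group assignments; otherwise a
#' tie-corrected normal approximation with continuity correction is used.
#'
#' @param x,y numeric vectors.
#' @param alternative `"less"` (x shifted below y) or `"greater"`.
#' @param exact_limit per-group size cutoff for the exact null (default 10).
#' @return list with `statistic` (rank sum of `x`), `p.value`, `exact`.
#' @examples
#' rank_sum_test(1:3, 4:6, alternative = "less")$p.value # 1/20
#' @export
rank_sum_test <- function(x, y,
                          alternative = c("less", "greater"),
                          exact_limit = 10L) {
  alternative <- match.arg(alternative)
  stopifnot(length(x) >= 1L, length(y) >= 1L)
  m <- length(x); n <- length(y); N <- m + n
  r <- rank(c(x, y))
  w <- sum(r[seq_len(m)])
  if (m <= exact_limit && n <= exact_limit) {
    r2 <- as.integer(round(2 * r))
    dist <- .rank_sum_exact_dist(r2, m)
    w2 <- as.integer(round(2 * w))
    tot <- choose(N, m)
    p <- if (alternative == "less") {
      sum(dist[seq_len(w2 + 1L)]) / tot
    } else {
      sum(dist[(w2 + 1L):length(dist)]) / tot
    }
    return(list(statistic = w, p.value = min(p, 1), exact = TRUE))
  }
  ew <- m * (N + 1) / 2
  tie_tab <- table(r)
  vw <- m * n / 12 * ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
  cc <- 0.5
  p <- if (alternative == "less") {
    stats::pnorm((w - ew + cc) / sqrt(vw))
  } else {
    stats::pnorm((w - ew - cc) / sqrt(vw), lower.tail = FALSE)
  }
  list(statistic = w, p.value = p, exact = FALSE)
}
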
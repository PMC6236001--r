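#' Exact lower-tail probability of the signed-rank statistic
#'
#' Distribution of \eqn{W^- = \sum_{i: s_i = -} r_i} when each of the n
#' ranks independently receives a uniform random sign, conditional on the
#' observed rank vector (so tied average ranks, which are half-integers,
#' are handled exactly). All \eqn{2^n} sign assignments are enumerated: the
#' vector of attainable \eqn{W^-} values is doubled rank by rank, which is
#' the full enumeration laid out breadth-first.
#'
#' @param ranks positive ranks, possibly tied (half-integer averages).
#' @param w threshold.
#' @return \eqn{P(W^- \le w)} under the null of random signs.
#' @export
exact_tail <- function(ranks, w) {
  n <- length(ranks)
  stopifnot(n >= 1, all(ranks > 0))
  if (n > 20) {
    msnet_error("TooLarge", "exact enumeration supported for n <= 20 pairs")
  }
  sums <- 0
  for (r in ranks) sums <- c(sums, sums + r)
  mean(sums <= w + 1e-9)
}

#' Exact two-sided Wilcoxon signed-rank test
#'
#' Paired nonparametric comparison used to decide whether one pooling
#' variant's per-run metrics systematically exceed another's. The procedure
#' is the classical one: zero differences are dropped, the absolute
#' differences are ranked with average ranks for ties, and the exact
#' two-sided p-value is computed by full enumeration of all sign
#' assignments conditional on the observed (tied) rank vector:
#' \eqn{p = \min(1, 2 P(W \le \min(W^+, W^-)))}.
#'
#' No normal approximation or continuity correction is ever applied; with
#' n = 10 paired runs the exact null distribution is the appropriate
#' reference, and metric vectors rounded to two decimals routinely produce
#' both zeros and ties that the approximate formulas handle poorly.
#'
#' @param x,y paired numeric vectors of equal length.
#' @return an object of class `wilcoxon_result`: a list with `w_minus`,
#'   `w_plus`, `statistic` (min of the two), `n_effective` (pairs remaining
#'   after zero-difference removal) and `p_two_sided`.
#' @examples
#' signed_rank_test(c(5, 6, 7), c(1, 2, 3))
#' @export
signed_rank_test <- function(x, y) {
  if (length(x) != length(y)) {
    msnet_error("LengthMismatch", "paired samples must have equal length")
  }
  stopifnot(length(x) >= 1)
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    res <- list(w_minus = 0, w_plus = 0, statistic = 0, n_effective = 0L,
                p_two_sided = 1)
    class(res) <- "wilcoxon_result"
    return(res)
  }
  rk <- rank(abs(d))
  w_minus <- sum(rk[d < 0])
  w_plus <- sum(rk[d > 0])
  w <- min(w_minus, w_plus)
  p <- min(1, 2 * exact_tail(rk, w))
  res <- list(w_minus = w_minus, w_plus = w_plus, statistic = w,
              n_effective = as.integer(n), p_two_sided = p)
  class(res) <- "wilcoxon_result"
  res
}

#' @export
print.wilcoxon_result <- function(x, ...) {
  cat(sprintf(
    "Exact Wilcoxon signed-rank test: W = %g (W+ = %g, W- = %g), n = %d, p = %.4f\n",
    x$statistic, x$w_plus, x$w_minus, x$n_effective, x$p_two_sided))
  invisible(x)
}
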
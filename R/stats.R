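#' One-sided hypergeometric upper tail
#'
#' Probability of drawing at least `k` successes when `n` items are drawn
#' without replacement from a population of `N` items containing `K`
#' successes, i.e. \eqn{P(X \ge k)} for
#' \eqn{X \sim \mathrm{Hypergeom}(N, K, n)}.  Evaluated in log-gamma space
#' via [stats::phyper()].  All arguments recycle.
#'
#' @param k Observed overlap (threshold), `0 <= k <= min(K, n)`.
#' @param K Number of successes in the population.
#' @param n Number of draws.
#' @param N Population size.
#' @return Probabilities in `(0, 1]`.
#' @examples
#' hypergeomRightTail(2, 2, 2, 10)  # 1/45
#' @export
hypergeomRightTail <- function(k, K, n, N) {
  r <- suppressWarnings(cbind(k, K, n, N))
  dimnames(r) <- NULL  # recycle & validate together
  k <- r[, 1]; K <- r[, 2]; n <- r[, 3]; N <- r[, 4]
  if (anyNA(r) || any(r < 0)) stop("hypergeometric arguments must be non-negative")
  if (any(K > N) || any(n > N)) stop("infeasible margins: K and n must not exceed N")
  if (any(k > pmin(K, n))) stop("infeasible overlap: k exceeds min(K, n)")
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  pmin(pmax(p, 0), 1)
}

#' One-sided Fisher exact test (right tail on the top-left cell)
#'
#' For the 2x2 table `rbind(c(a, b), c(c, d))` with all margins fixed,
#' returns the probability that the top-left cell is at least `a`.
#' Equivalent to `hypergeomRightTail(a, a + c, a + b, a + b + c + d)`.
#' The degenerate all-zero table returns 1.
#'
#' @param a,b,c,d Non-negative cell counts (vectorised).
#' @return One-sided p-values in `(0, 1]`.
#' @examples
#' fisherRightTail(2, 0, 0, 8)  # 1/45
#' @export
fisherRightTail <- function(a, b, c, d) {
  r <- suppressWarnings(cbind(a, b, c, d))
  dimnames(r) <- NULL
  if (anyNA(r) || any(r < 0)) stop("cell counts must be non-negative")
  a <- r[, 1]; b <- r[, 2]; c <- r[, 3]; d <- r[, 4]
  hypergeomRightTail(a, a + c, a + b, a + b + c + d)
}

#' q-values for multiple-testing control
#'
#' Storey-style q-values: \eqn{\hat\pi_0} is estimated on the grid
#' \eqn{\lambda = 0.05, 0.10, \dots, 0.95} and smoothed with a cubic
#' smoothing spline (df = 3) evaluated at \eqn{\lambda = 0.95}; q-values
#' are then \eqn{\hat\pi_0} times the Benjamini-Hochberg step-up values.
#' When fewer than 100 p-values are supplied, or the \eqn{\hat\pi_0}
#' estimate falls outside (0, 1], the method falls back to plain
#' Benjamini-Hochberg (\eqn{\pi_0 = 1}), which keeps small inputs
#' well-defined.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return q-values, same length and order as `p`; monotone in `p`.
#' @examples
#' qvalues(c(0.01, 0.02, 0.03, 0.04))  # BH fallback: all 0.04
#' @export
qvalues <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  pi0 <- 1
  if (m >= 100) {
    lambda <- seq(0.05, 0.95, by = 0.05)
    cnt <- vapply(lambda, function(l) sum(p > l), numeric(1))
    pi0Lambda <- cnt / (m * (1 - lambda))
    fit <- stats::smooth.spline(lambda, pi0Lambda, df = 3)
    pi0Hat <- stats::predict(fit, x = 0.95)$y
    if (is.finite(pi0Hat) && pi0Hat > 0 && pi0Hat <= 1) pi0 <- pi0Hat
  }
  o <- order(p, decreasing = TRUE)
  q <- pmin(1, pi0 * p[o] * m / (m:1))
  q <- cummin(q)
  q[order(o)]
}

#' Binomial upper tail
#'
#' \eqn{P(X \ge k)} for \eqn{X \sim \mathrm{Binomial}(n, prob)}, i.e.
#' \eqn{\sum_{j=k}^{n} \binom{n}{j} prob^j (1-prob)^{n-j}}.
#'
#' @param n Number of trials.
#' @param k Threshold count, `0 <= k <= n`.
#' @param prob Success probability.
#' @return Probability in `[0, 1]`.
#' @examples
#' binomRightTail(26, 14, 0.756)
#' @export
binomRightTail <- function(n, k, prob) {
  r <- suppressWarnings(cbind(n, k, prob))
  dimnames(r) <- NULL
  n <- r[, 1]; k <- r[, 2]; prob <- r[, 3]
  if (anyNA(r) || any(n < 0) || any(k < 0)) stop("counts must be non-negative")
  if (any(k > n)) stop("threshold k exceeds the number of trials")
  if (any(prob < 0 | prob > 1)) stop("prob must lie in [0, 1]")
  stats::pbinom(k - 1, n, prob, lower.tail = FALSE)
}

#' Standard normal upper tail
#'
#' Survival function of the standard normal, accurate in relative terms
#' deep into the tail (delegates to [stats::pnorm()] with
#' `lower.tail = FALSE`, which works in log space).
#'
#' @param z Numeric vector of z-scores.
#' @return \eqn{P(Z \ge z)} for standard normal Z.
#' @examples
#' normalRightTail(1.65)  # ~0.0495
#' @export
normalRightTail <- function(z) {
  if (anyNA(z) || any(!is.finite(z))) stop("z must be finite")
  stats::pnorm(z, lower.tail = FALSE)
}

#' Pearson correlation with two-sided significance
#'
#' @param x,y Numeric vectors of equal length (at least 3), neither
#'   constant.
#' @return List with `estimate` (correlation in `[-1, 1]`) and `p.value`
#'   (two-sided, from the t transform with n - 2 degrees of freedom).
#' @examples
#' pearsonWithP(c(1, 2, 3, 4), c(1, 3, 2, 4))
#' @export
pearsonWithP <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant vector")
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(estimate = unname(ct$estimate), p.value = ct$p.value)
}

# p-value floor applied before any log so that -log p stays finite.
PVAL_FLOOR <- 1e-320

clampP <- function(p) pmax(p, PVAL_FLOOR)
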
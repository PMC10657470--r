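# Power of a one-sample Spearman correlation test.

#' Power of a Spearman correlation test
#'
#' `fisher_z` mode applies the Fisher z approximation used for Pearson
#' correlations to the Spearman coefficient (the convention of standard
#' power packages):
#' `power = Phi(sqrt(n-3) * atanh(rho) - z_{1-alpha/2}) +
#'          Phi(-sqrt(n-3) * atanh(rho) - z_{1-alpha/2})`.
#' `simulation` mode is the ground truth: bivariate normal samples are
#' drawn with Pearson correlation `2*sin(pi*rho/6)` — so their population
#' Spearman correlation equals `rho` — and the rejection rate of the
#' two-sided Spearman test at `alpha` is returned.
#'
#' @param rho target Spearman correlation, in (-1, 1).
#' @param n sample size, at least 4.
#' @param alpha two-sided significance level (default 0.05).
#' @param method `"fisher_z"` (default) or `"simulation"`.
#' @param n_sims simulation draws (default 10000).
#' @param seed simulation seed.
#' @return power in `[0, 1]`.
#' @examples
#' spearman_power(0.5, 51)        # ~0.97
#' @export
spearman_power <- function(rho, n, alpha = 0.05,
                           method = c("fisher_z", "simulation"),
                           n_sims = 10000, seed = 0) {
  method <- match.arg(method)
  if (!is.finite(rho) || abs(rho) >= 1)
    stop("validation error: rho must lie strictly in (-1, 1)")
  if (!is.finite(n) || n < 4) stop("validation error: n must be >= 4")
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop("validation error: alpha must lie in (0, 1)")
  if (method == "fisher_z") {
    z <- sqrt(n - 3) * atanh(rho)
    zc <- stats::qnorm(1 - alpha / 2)
    return(stats::pnorm(z - zc) + stats::pnorm(-z - zc))
  }
  set.seed(seed)
  r <- 2 * sin(pi * rho / 6)
  rej <- 0L
  for (i in seq_len(n_sims)) {
    x <- stats::rnorm(n)
    y <- r * x + sqrt(1 - r^2) * stats::rnorm(n)
    p <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                          exact = FALSE)$p.value)
    if (p < alpha) rej <- rej + 1L
  }
  rej / n_sims
}

#' Smallest sample size reaching a target power
#'
#' Integer search (doubling bracket plus bisection) over the `fisher_z`
#' power, which is monotone increasing in `n`: returns the smallest `n`
#' with `power(n) >= target_power` (and `power(n-1) < target_power`
#' whenever `n > 4`).
#'
#' @param rho target Spearman correlation.
#' @param alpha two-sided significance level.
#' @param target_power required power, strictly below 1.
#' @param n_max search cap (default 1e6).
#' @return integer sample size.
#' @export
minimum_n <- function(rho, alpha = 0.05, target_power = 0.8, n_max = 1e6) {
  if (target_power >= 1 || target_power <= 0)
    stop("validation error: target_power must lie in (0, 1)")
  if (abs(rho) >= 1 || abs(rho) <= 0)
    stop("validation error: rho must be nonzero and strictly in (-1, 1)")
  pw <- function(n) spearman_power(rho, n, alpha, method = "fisher_z")
  lo <- 4L
  if (pw(lo) >= target_power) return(lo)
  hi <- 8L
  while (pw(hi) < target_power) {
    lo <- hi
    hi <- hi * 2L
    if (hi > n_max) stop("bounded-search error: target power unreachable by n = ", n_max)
  }
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (pw(mid) >= target_power) hi <- mid else lo <- mid
  }
  hi
}
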
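# Statistical primitives used throughout: Fisher's exact test (two-sided,
# point-probability rule), hypergeometric tails, BH adjustment, Welch t,
# coefficient of variation, two-group log-rank.

#' Fisher's exact test for a 2x2 table (two-sided)
#'
#' Conditional on both margins, the p-value sums the probabilities of all
#' tables whose point probability does not exceed that of the observed table
#' (the point-probability convention, as in `stats::fisher.test`; a relative
#' slack of 1e-7 guards against floating-point ties).  Degenerate margins
#' (an empty row or column) give p = 1.
#'
#' @param a,b,c,d cell counts of the table `rbind(c(a, b), c(c, d))`; vectors
#'   are accepted and processed elementwise.
#' @return for scalar input a list with `statistic` (sample odds ratio) and
#'   `p`; for vector input the numeric vector of p-values.
#' @export
fisher_exact_two_sided <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0) || any(c(a, b, c, d) != floor(c(a, b, c, d))))
    stop("cell counts must be non-negative integers")
  p <- mapply(fisher2x2_p, a, b, c, d)
  if (length(a) == 1L) list(statistic = (a * d) / (b * c), p = p) else p
}

fisher2x2_p <- function(a, b, c, d) {
  m1 <- a + b   # row 1 margin
  k <- a + c    # column 1 margin
  n <- a + b + c + d
  if (m1 == 0 || m1 == n || k == 0 || k == n) return(1)
  lo <- max(0L, k - (c + d))
  hi <- min(k, m1)
  x <- lo:hi
  dens <- dhyper(x, m1, c + d, k)
  obs <- dens[a - lo + 1L]
  min(1, sum(dens[dens <= obs * (1 + 1e-7)]))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up adjustment, capped at 1, returned in the input order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values (q-values).
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Hypergeometric tail probabilities
#'
#' For X ~ Hypergeometric(N, K, n) (k successes in a draw of n from a
#' population of N containing K successes): `upper` is P(X >= k), `lower` is
#' P(X <= k); both include the point mass at k.
#'
#' @param N population size.
#' @param K number of successes in the population.
#' @param n draw size.
#' @param k observed successes.
#' @param tail `"upper"` or `"lower"`.
#' @return tail probability.
#' @export
hypergeom_tail <- function(N, K, n, k, tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  if (K > N || n > N) stop("need K <= N and n <= N")
  if (k < 0 || k > min(K, n)) stop("infeasible k: need 0 <= k <= min(K, n)")
  if (tail == "upper") {
    phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  } else {
    phyper(k, K, N - K, n)
  }
}

#' Welch (or pooled) two-sample t-test
#'
#' Welch with Satterthwaite degrees of freedom by default; `pooled = TRUE`
#' switches to the equal-variance statistic.  Degenerate inputs are handled
#' without error: both groups constant with equal means gives p = 1, unequal
#' means with zero variance gives p = 0.
#'
#' @param x,y numeric vectors (each length >= 2).
#' @param alternative `"two.sided"`, `"greater"` (mean x > mean y) or `"less"`.
#' @param pooled use the pooled-variance statistic instead of Welch.
#' @return list with `statistic` and `p`.
#' @export
welch_t <- function(x, y, alternative = c("two.sided", "greater", "less"),
                    pooled = FALSE) {
  alternative <- match.arg(alternative)
  if (length(x) < 2 || length(y) < 2) stop("both groups need >= 2 observations")
  if (sd(x) == 0 && sd(y) == 0) {
    if (mean(x) == mean(y)) return(list(statistic = 0, p = 1))
    sgn <- sign(mean(x) - mean(y))
    p <- switch(alternative, two.sided = 0,
                greater = if (sgn > 0) 0 else 1,
                less = if (sgn < 0) 0 else 1)
    return(list(statistic = sgn * Inf, p = p))
  }
  res <- t.test(x, y, alternative = alternative, var.equal = pooled)
  list(statistic = unname(res$statistic), p = res$p.value)
}

#' Coefficient of variation
#'
#' Sample standard deviation (n - 1) over the absolute mean.  A zero mean
#' returns `Inf` (such partners sort last when panels are ranked by CV).
#'
#' @param v numeric vector, length >= 2.
#' @return non-negative real (possibly `Inf`).
#' @export
coefficient_of_variation <- function(v) {
  if (length(v) < 2) stop("CV needs >= 2 values")
  m <- mean(v)
  if (m == 0) return(Inf)
  sd(v) / abs(m)
}

#' Two-group log-rank test
#'
#' Standard log-rank chi-square with 1 df via `survival::survdiff`.  With no
#' events at all the test is vacuous and p = 1.
#'
#' @param times positive follow-up times.
#' @param events 0/1 event indicators.
#' @param groups two-level group labels.
#' @return list with `statistic` (chi-square) and `p`.
#' @export
logrank <- function(times, events, groups) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) != 2) stop("log-rank needs exactly two non-empty groups")
  if (any(times <= 0)) stop("times must be positive")
  if (sum(events) == 0) return(list(statistic = 0, p = 1))
  fit <- survival::survdiff(survival::Surv(times, events) ~ groups)
  chisq <- unname(fit$chisq)
  list(statistic = chisq, p = pchisq(chisq, df = 1, lower.tail = FALSE))
}
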
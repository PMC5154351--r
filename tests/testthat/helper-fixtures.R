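# Shared fixture builders and independent oracles used across test files.

# Small expression matrix with named dims.
toy_matrix <- function(values, features = NULL, samples = NULL, scale = "log2") {
  m <- if (is.matrix(values)) values else matrix(values, nrow = length(features))
  if (is.null(features)) features <- rownames(m) %||% sprintf("f%02d", seq_len(nrow(m)))
  if (is.null(samples)) samples <- colnames(m) %||% sprintf("s%02d", seq_len(ncol(m)))
  dimnames(m) <- list(features, samples)
  expression_matrix(m, scale = scale)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent two-sided Fisher oracle: explicit enumeration over all tables
# with the observed margins, point probabilities from choose() directly.
fisher_oracle <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c; n <- m1 + m2
  if (m1 == 0 || m2 == 0 || k == 0 || k == n) return(1)
  xs <- max(0, k - m2):min(k, m1)
  probs <- choose(m1, xs) * choose(m2, k - xs) / choose(n, k)
  obs <- probs[xs == a]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Independent hypergeometric pmf via choose().
hyper_pmf_oracle <- function(N, K, n) {
  ks <- 0:min(K, n)
  choose(K, ks) * choose(N - K, n - ks) / choose(N, n)
}

# Textbook log-rank tabulation (two groups, right-censored), independent of
# survival::survdiff.
logrank_oracle <- function(times, events, groups) {
  groups <- as.integer(as.factor(groups))
  o1 <- 0; e1 <- 0; v <- 0
  for (t in sort(unique(times[events == 1]))) {
    at_risk <- times >= t
    n <- sum(at_risk); n1 <- sum(at_risk & groups == 1)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & groups == 1)
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (o1 - e1)^2 / v
}

# Default synthetic cohort, memoised per session (several tests reuse it).
default_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_cohort(cohort_config())
    cache
  }
})

# Planted-truth confusion of a call matrix against a truth incidence.
truth_confusion <- function(calls, truth) {
  cm <- matrix(0L, nrow(truth), ncol(truth), dimnames = dimnames(truth))
  shared <- intersect(rownames(calls$calls), rownames(truth))
  cm[shared, ] <- calls$calls[shared, colnames(truth), drop = FALSE]
  planted <- truth != 0L
  list(se = sum(planted & cm == truth) / sum(planted),
       sp = sum(!planted & cm == 0L) / sum(!planted))
}
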
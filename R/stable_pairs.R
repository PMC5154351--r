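# Steps 1-2 of the work-flow: stable-pair mining in normal samples and
# Fisher-exact reversal detection against the tumor cohort.

#' Compare two expression values within a sample
#'
#' Strict comparison; exactly equal values are a tie.  Ties count against
#' stability (as a violation of the stable ordering) and never as a vote.
#'
#' @param a,b numeric scalars.
#' @return `"less"`, `"greater"` or `"tie"`.
#' @export
compare_ordering <- function(a, b) {
  if (!is.finite(a) || !is.finite(b)) stop("values must be finite")
  if (a < b) "less" else if (a > b) "greater" else "tie"
}

# Count, for every ordered pair (i, j), the samples where row i < row j
# strictly.  Returns an n_feature x n_feature integer matrix.
pair_less_counts <- function(m) {
  nf <- nrow(m)
  counts <- matrix(0L, nf, nf, dimnames = list(rownames(m), rownames(m)))
  for (s in seq_len(ncol(m))) {
    x <- m[, s]
    counts <- counts + outer(x, x, "<")
  }
  counts
}

#' Find stably ordered miRNA pairs in normal samples
#'
#' For each unordered pair the majority orientation is assessed; the pair is
#' stable when its support (fraction of normal samples showing the ordering,
#' ties counting as violations) strictly exceeds `threshold`.
#'
#' @param normals expression matrix of normal samples (>= 2 columns).
#' @param threshold stability threshold (default 0.95; the ordering must hold
#'   in more than 95% of normals).
#' @return data.frame with columns `low`, `high` (ids with
#'   expr(low) < expr(high) in normals), `support`, `n_normal`.
#' @export
find_stable_pairs <- function(normals, threshold = 0.95) {
  if (ncol(normals) < 2) stop("need >= 2 normal samples")
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0, 1)")
  n <- ncol(normals)
  counts <- pair_less_counts(normals)
  ids <- rownames(normals)
  ut <- which(upper.tri(counts), arr.ind = TRUE)  # i < j, one row per unordered pair
  c_ij <- counts[ut]                               # support for ids[i] < ids[j]
  c_ji <- counts[cbind(ut[, 2], ut[, 1])]
  fwd <- c_ij >= c_ji
  supp <- ifelse(fwd, c_ij, c_ji) / n
  keep <- supp > threshold
  data.frame(
    low = ifelse(fwd, ids[ut[, 1]], ids[ut[, 2]])[keep],
    high = ifelse(fwd, ids[ut[, 2]], ids[ut[, 1]])[keep],
    support = supp[keep],
    n_normal = rep_len(n, sum(keep)),
    stringsAsFactors = FALSE
  )
}

# Vectorised reversal testing of all stable pairs at once.  "Flip" means the
# stable ordering low < high does not hold (ties fall into the flip cell).
reversal_tests <- function(stable, normals, cancers) {
  if (ncol(cancers) < 1) stop("cancer cohort is empty")
  missing <- setdiff(unique(c(stable$low, stable$high)), rownames(cancers))
  if (length(missing)) stop("cancer matrix lacks features: ", paste(head(missing, 5), collapse = ", "))
  nk <- integer(nrow(stable)); ck <- integer(nrow(stable))
  for (s in seq_len(ncol(normals))) {
    x <- normals[, s]
    nk <- nk + (x[stable$low] < x[stable$high])
  }
  for (s in seq_len(ncol(cancers))) {
    x <- cancers[, s]
    ck <- ck + (x[stable$low] < x[stable$high])
  }
  nn <- ncol(normals); nc <- ncol(cancers)
  out <- stable
  out$normal_keep <- nk
  out$normal_flip <- nn - nk
  out$cancer_keep <- ck
  out$cancer_flip <- nc - ck
  out$p <- if (nrow(out)) mapply(fisher2x2_p, nk, nn - nk, ck, nc - ck) else numeric(0)
  out
}

#' Test one stable pair for ordering reversal in tumors
#'
#' Builds the 2x2 table `[[normal_keep, normal_flip], [cancer_keep,
#' cancer_flip]]` ("flip": the stable ordering `low < high` does not hold in
#' the sample; ties count as flips) and applies the two-sided Fisher test.
#'
#' @param sp one-row data.frame (or list) with `low` and `high` ids.
#' @param normals,cancers expression matrices containing both miRNAs.
#' @return list with the four cell counts, flip fractions and the Fisher `p`.
#' @export
fisher_reversal_test <- function(sp, normals, cancers) {
  if (ncol(cancers) < 1) stop("cancer cohort is empty")
  nk <- sum(normals[sp$low, ] < normals[sp$high, ])
  ck <- sum(cancers[sp$low, ] < cancers[sp$high, ])
  nf <- ncol(normals) - nk; cf <- ncol(cancers) - ck
  list(low = sp$low, high = sp$high,
       normal_keep = nk, normal_flip = nf, cancer_keep = ck, cancer_flip = cf,
       normal_flip_frac = nf / ncol(normals), cancer_flip_frac = cf / ncol(cancers),
       p = fisher2x2_p(nk, nf, ck, cf))
}

#' Select significant reversal pairs at an FDR cutoff
#'
#' BH adjustment is computed across all tested stable pairs; a pair is kept
#' when `q < fdr` and its tumor flip fraction exceeds its normal flip
#' fraction (the reversal must point toward the tumors).
#'
#' @param candidates data.frame from the reversal tests (columns
#'   `normal_keep`, `normal_flip`, `cancer_keep`, `cancer_flip`, `p`).
#' @param fdr FDR cutoff (default 0.1).
#' @return subset of `candidates` with a `q` column added.
#' @export
select_reversal_pairs <- function(candidates, fdr = 0.1) {
  candidates$q <- bh_adjust(candidates$p)
  nflip <- candidates$normal_flip / (candidates$normal_keep + candidates$normal_flip)
  cflip <- candidates$cancer_flip / (candidates$cancer_keep + candidates$cancer_flip)
  candidates[candidates$q < fdr & cflip > nflip, , drop = FALSE]
}
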
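# Steps 3-4 of the work-flow: direction assignment, panel construction from
# direction-consistent reversal pairs ranked by partner CV, and
# majority-vote individual calling.

#' Group-level deregulation directions
#'
#' Per miRNA the direction is the sign of (mean over tumor samples - mean
#' over normal samples); `stat = "median"` uses medians for the effect.  A
#' deregulation direction presupposes deregulation: the direction is `none`
#' unless the group difference is significant (per-miRNA Welch test at
#' `alpha`).  Set `alpha = NULL` to use the raw effect sign (direction
#' `none` only at an exactly zero effect).
#'
#' @param cancers,normals expression matrices sharing feature ids.
#' @param stat `"mean"` (default) or `"median"`.
#' @param alpha significance level for calling a direction (default 0.05);
#'   `NULL` disables the test.
#' @return data.frame with `mirna`, `effect`, `p`, `direction`
#'   (`up`/`down`/`none`).
#' @export
compute_directions <- function(cancers, normals, stat = c("mean", "median"),
                               alpha = 0.05) {
  stat <- match.arg(stat)
  feats <- rownames(cancers)
  if (!setequal(feats, rownames(normals)))
    stop("cancers and normals must share the same feature set")
  normals <- normals[feats, , drop = FALSE]
  eff <- if (stat == "mean") rowMeans(cancers) - rowMeans(normals)
         else apply(cancers, 1, median) - apply(normals, 1, median)
  p <- if (ncol(cancers) >= 2 && ncol(normals) >= 2)
    row_welch_p2(cancers, normals)
  else rep(NA_real_, length(feats))
  dir <- ifelse(eff > 0, "up", ifelse(eff < 0, "down", "none"))
  if (!is.null(alpha)) dir[!is.na(p) & p >= alpha] <- "none"
  data.frame(mirna = feats, effect = unname(eff), p = unname(p),
             direction = dir, stringsAsFactors = FALSE)
}

#' Direction a reversal pair implies for one of its members
#'
#' Under the constant-partner hypothesis, a stable `low < high` ordering that
#' reverses in tumors implies `low` is upregulated (if `low` moved) or `high`
#' is downregulated (if `high` moved).
#'
#' @param rp reversal pair (list/row with `low`, `high`).
#' @param target one of the two member ids.
#' @return `"up"` or `"down"`.
#' @export
implied_direction <- function(rp, target) {
  if (target == rp$low) "up"
  else if (target == rp$high) "down"
  else stop("target '", target, "' is not a member of the pair")
}

#' Build per-miRNA panels of reversal partners
#'
#' Both members of each reversal pair are candidate targets.  A pair enters
#' target A's candidate set iff the direction it implies for A equals A's
#' group-level deregulation direction, so the reversal is attributed to the
#' member that actually moved (miRNAs without a deregulation direction never
#' receive panels; see [compute_directions()]).  Candidates are ranked by
#' the partner's coefficient of variation over all training samples
#' (ascending, ties broken by partner id) — the constant-partner hypothesis:
#' deregulated partners have inflated CV and sort last — and the top `k`
#' kept; miRNAs with no surviving pair get no panel.
#'
#' @param reversals data.frame of selected reversal pairs (`low`, `high`,
#'   optionally `p`, `q`, `support`).
#' @param directions data.frame from [compute_directions()].
#' @param training expression matrix over which partner CVs are computed
#'   (tumor + normal training samples pooled).
#' @param k maximal panel size (default 3).
#' @param cv_scale scale on which the coefficient of variation is computed:
#'   `"raw"` (default) exponentiates log2 matrices first, so CV measures
#'   relative expression variability and is comparable across expression
#'   levels; `"native"` uses the values as stored (on log2 data this makes
#'   CV depend on the arbitrary location of the log scale).
#' @return data.frame with one row per retained (target, partner) pair:
#'   `target`, `direction`, `partner`, `partner_cv`, `stable_low`,
#'   `stable_high`, `p`, `q`.
#' @export
build_panels <- function(reversals, directions, training, k = 3,
                         cv_scale = c("raw", "native")) {
  if (k < 1) stop("k must be >= 1")
  cv_scale <- match.arg(cv_scale)
  dir <- setNames(directions$direction, directions$mirna)
  cv_base <- if (cv_scale == "raw" && expr_scale(training) == "log2") 2^training
             else training
  cvs <- apply(cv_base, 1, coefficient_of_variation)
  rows <- list()
  for (side in c("low", "high")) {
    target <- reversals[[side]]
    partner <- reversals[[if (side == "low") "high" else "low"]]
    implied <- if (side == "low") "up" else "down"
    keep <- !is.na(dir[target]) & dir[target] == implied
    if (!any(keep)) next
    rows[[side]] <- data.frame(
      target = target[keep], direction = implied, partner = partner[keep],
      partner_cv = unname(cvs[partner[keep]]),
      stable_low = reversals$low[keep], stable_high = reversals$high[keep],
      p = if ("p" %in% names(reversals)) reversals$p[keep] else NA_real_,
      q = if ("q" %in% names(reversals)) reversals$q[keep] else NA_real_,
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(target = character(0), direction = character(0),
                      partner = character(0), partner_cv = numeric(0),
                      stable_low = character(0), stable_high = character(0),
                      p = numeric(0), q = numeric(0), stringsAsFactors = FALSE))
  panel <- do.call(rbind, rows)
  panel <- panel[order(panel$target, panel$partner_cv, panel$partner), , drop = FALSE]
  idx <- ave(seq_len(nrow(panel)), panel$target, FUN = seq_along)
  panel <- panel[idx <= k, , drop = FALSE]
  rownames(panel) <- NULL
  panel
}

#' Call one sample against one miRNA's panel
#'
#' A panel pair votes when the tumor-state ordering holds strictly in the
#' sample (for an up target: target > partner; for a down target:
#' target < partner; ties never vote).  The call is the panel direction iff
#' more than half of the pairs vote.
#'
#' @param sample named numeric vector of expression values.
#' @param panel rows of a panel data.frame for a single target.
#' @return list with `call` (`"up"`/`"down"`/`"none"`) and `votes`.
#' @export
call_sample <- function(sample, panel) {
  if (length(unique(panel$target)) != 1L) stop("panel must concern a single target")
  need <- unique(c(panel$target, panel$partner))
  if (anyNA(sample[need])) stop("sample lacks values for: ",
                                paste(need[is.na(sample[need])], collapse = ", "))
  tv <- sample[[panel$target[1]]]
  pv <- sample[panel$partner]
  votes <- if (panel$direction[1] == "up") sum(tv > pv) else sum(tv < pv)
  call <- if (votes > nrow(panel) / 2) panel$direction[1] else "none"
  list(call = call, votes = as.integer(votes))
}

#' Call every sample of a cohort against every panel
#'
#' @param cohort expression matrix containing all panel miRNAs.
#' @param panels panel data.frame from [build_panels()].
#' @return object of class `reo_calls`: list with integer matrices `calls`
#'   (+1 up / -1 down / 0 none) and `votes` (miRNA x sample), named integer
#'   vector `panel_size` and character vector `direction` per target.
#' @export
call_cohort <- function(cohort, panels) {
  targets <- unique(panels$target)
  need <- unique(c(panels$target, panels$partner))
  missing <- setdiff(need, rownames(cohort))
  if (length(missing)) stop("cohort lacks panel miRNAs: ", paste(missing, collapse = ", "))
  nsamp <- ncol(cohort)
  if (!length(targets)) {
    return(structure(list(calls = matrix(0L, 0, nsamp, dimnames = list(NULL, colnames(cohort))),
                          votes = matrix(0L, 0, nsamp, dimnames = list(NULL, colnames(cohort))),
                          panel_size = integer(0), direction = character(0)),
                     class = "reo_calls"))
  }
  tmat <- cohort[panels$target, , drop = FALSE]
  pmat <- cohort[panels$partner, , drop = FALSE]
  up <- panels$direction == "up"
  hold <- matrix(FALSE, nrow(panels), nsamp)
  hold[up, ] <- tmat[up, , drop = FALSE] > pmat[up, , drop = FALSE]
  hold[!up, ] <- tmat[!up, , drop = FALSE] < pmat[!up, , drop = FALSE]
  votes <- rowsum(hold + 0L, group = panels$target, reorder = FALSE)
  size <- as.integer(table(factor(panels$target, levels = rownames(votes))))
  names(size) <- rownames(votes)
  dirn <- setNames(panels$direction[!duplicated(panels$target)],
                   panels$target[!duplicated(panels$target)])[rownames(votes)]
  calls <- (votes > size / 2) * ifelse(dirn == "up", 1L, -1L)
  storage.mode(calls) <- "integer"
  storage.mode(votes) <- "integer"
  colnames(calls) <- colnames(votes) <- colnames(cohort)
  structure(list(calls = calls, votes = votes, panel_size = size, direction = dirn),
            class = "reo_calls")
}

#' @export
print.reo_calls <- function(x, ...) {
  cat("Individual-level REO calls: ", nrow(x$calls), " miRNAs x ",
      ncol(x$calls), " samples\n", sep = "")
  cat("  up calls:   ", sum(x$calls == 1L), "\n", sep = "")
  cat("  down calls: ", sum(x$calls == -1L), "\n", sep = "")
  cat("  call rate:  ", signif(mean(x$calls != 0L), 3), "\n", sep = "")
  invisible(x)
}

#' @export
summary.reo_calls <- function(object, ...) {
  per_sample <- colSums(object$calls != 0L)
  per_mirna <- rowSums(object$calls != 0L)
  out <- list(n_mirna = nrow(object$calls), n_sample = ncol(object$calls),
              call_rate = mean(object$calls != 0L),
              mean_calls_per_sample = mean(per_sample),
              mean_samples_per_mirna = mean(per_mirna))
  class(out) <- "summary.reo_calls"
  out
}

#' @export
print.summary.reo_calls <- function(x, ...) {
  cat("REO call summary\n")
  cat("  miRNAs with panels:     ", x$n_mirna, "\n", sep = "")
  cat("  samples:                ", x$n_sample, "\n", sep = "")
  cat("  overall call rate:      ", signif(x$call_rate, 3), "\n", sep = "")
  cat("  mean calls per sample:  ", signif(x$mean_calls_per_sample, 4), "\n", sep = "")
  cat("  mean samples per miRNA: ", signif(x$mean_samples_per_mirna, 4), "\n", sep = "")
  invisible(x)
}

#' Write a call matrix as TSV (+1 / -1 / 0 cells)
#' @param calls `reo_calls` object.
#' @param path output path.
#' @export
write_call_matrix <- function(calls, path) {
  df <- data.frame(mirna_id = rownames(calls$calls), calls$calls,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
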
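# The model interface: fit the full training work-flow and predict calls on
# new cohorts.

#' Fit a rank-reversal model on paired training cohorts
#'
#' Runs the four training steps: (1) stable-pair mining in the normal
#' samples; (2) Fisher-exact reversal testing of every stable pair against
#' the tumor cohort with BH FDR control; (3) panel construction — each
#' reversal pair is attributed to the member whose implied direction matches
#' its group-level direction, partners are ranked by coefficient of variation
#' over the pooled training samples and the `k` least variable kept; (4) the
#' fitted panels call individual samples by majority vote (see
#' [predict.reo_fit()]).
#'
#' @param normals expression matrix of normal training samples.
#' @param tumors expression matrix of tumor training samples (same features).
#' @param stability stable-pair support threshold (default 0.95, strict).
#' @param fdr reversal-pair FDR cutoff (default 0.1).
#' @param k maximal panel size (default 3).
#' @param direction_stat `"mean"` or `"median"` for group-level directions.
#' @param direction_alpha significance level for the group-level deregulation
#'   direction (see [compute_directions()]; `NULL` for the raw sign rule).
#' @param cv_scale scale for partner CV computation, see [build_panels()].
#' @param min_panel minimal panel size to retain a miRNA (default 1).
#' @return object of class `reo_fit` with components `stable_pairs`,
#'   `reversal_tests` (all candidates with `p`, `q`), `reversal_pairs`
#'   (selected), `directions`, `panels`, `params`, `n_normal`, `n_tumor`.
#' @examples
#' syn <- generate_cohort(cohort_config(n_mirnas = 40, n_normal = 25,
#'                                      n_tumor = 25, n_de_mirnas = 6, seed = 1))
#' fit <- reo_fit(syn$normals, syn$tumors)
#' fit
#' calls <- predict(fit, syn$tumors)
#' summary(calls)
#' @export
reo_fit <- function(normals, tumors, stability = 0.95, fdr = 0.1, k = 3,
                    direction_stat = c("mean", "median"), direction_alpha = 0.05,
                    cv_scale = c("raw", "native"), min_panel = 1) {
  direction_stat <- match.arg(direction_stat)
  if (!setequal(rownames(normals), rownames(tumors)))
    stop("normals and tumors must share the same feature set")
  tumors <- tumors[rownames(normals), , drop = FALSE]
  stable <- find_stable_pairs(normals, threshold = stability)
  cand <- reversal_tests(stable, normals, tumors)
  cand$q <- bh_adjust(cand$p)
  selected <- select_reversal_pairs(cand[setdiff(names(cand), "q")], fdr = fdr)
  directions <- compute_directions(tumors, normals, stat = direction_stat,
                                   alpha = direction_alpha)
  training <- cbind(normals, tumors)
  colnames(training) <- make.unique(colnames(training))
  attr(training, "scale") <- expr_scale(normals)
  panels <- build_panels(selected, directions, training, k = k, cv_scale = cv_scale)
  if (min_panel > 1 && nrow(panels)) {
    sizes <- table(panels$target)
    panels <- panels[panels$target %in% names(sizes)[sizes >= min_panel], , drop = FALSE]
  }
  structure(list(stable_pairs = stable, reversal_tests = cand,
                 reversal_pairs = selected, directions = directions,
                 panels = panels,
                 params = list(stability = stability, fdr = fdr, k = k,
                               direction_stat = direction_stat,
                               direction_alpha = direction_alpha, min_panel = min_panel),
                 n_normal = ncol(normals), n_tumor = ncol(tumors),
                 features = rownames(normals)),
            class = "reo_fit")
}

#' @export
print.reo_fit <- function(x, ...) {
  cat("Rank-reversal individual DE model (reo_fit)\n")
  cat("  training: ", x$n_normal, " normal / ", x$n_tumor, " tumor samples, ",
      length(x$features), " miRNAs\n", sep = "")
  cat("  stable pairs (support > ", x$params$stability, "): ",
      nrow(x$stable_pairs), "\n", sep = "")
  cat("  reversal pairs (FDR < ", x$params$fdr, "): ",
      nrow(x$reversal_pairs), "\n", sep = "")
  cat("  panel pairs (top ", x$params$k, " by partner CV): ", nrow(x$panels),
      " covering ", length(unique(x$panels$target)), " miRNAs\n", sep = "")
  invisible(x)
}

#' @export
summary.reo_fit <- function(object, ...) {
  sizes <- if (nrow(object$panels)) table(object$panels$target) else integer(0)
  out <- list(
    n_features = length(object$features),
    n_stable = nrow(object$stable_pairs),
    n_reversal = nrow(object$reversal_pairs),
    n_panel_pairs = nrow(object$panels),
    n_callable = length(unique(object$panels$target)),
    panel_size_dist = if (length(sizes)) table(as.integer(sizes)) else table(integer(0)),
    params = object$params)
  class(out) <- "summary.reo_fit"
  out
}

#' @export
print.summary.reo_fit <- function(x, ...) {
  cat("reo_fit stage counts (stable >= reversal >= panel targets)\n")
  cat("  miRNAs measured:  ", x$n_features, "\n", sep = "")
  cat("  stable pairs:     ", x$n_stable, "\n", sep = "")
  cat("  reversal pairs:   ", x$n_reversal, "\n", sep = "")
  cat("  panel pairs:      ", x$n_panel_pairs, "\n", sep = "")
  cat("  callable miRNAs:  ", x$n_callable, "\n", sep = "")
  if (length(x$panel_size_dist)) {
    cat("  panel sizes:      ")
    print(x$panel_size_dist)
  }
  invisible(x)
}

#' Panel table of a fitted model
#'
#' @param object a `reo_fit`.
#' @param ... unused.
#' @return the panel data.frame (one row per target-partner pair).
#' @export
coef.reo_fit <- function(object, ...) object$panels

#' Call individual samples with a fitted rank-reversal model
#'
#' @param object a `reo_fit`.
#' @param newdata expression matrix containing every panel miRNA (any sample
#'   set; no normalization against the training data is needed since only
#'   within-sample orderings are read).
#' @param ... unused.
#' @return a [call_cohort()] result (`reo_calls`).
#' @export
predict.reo_fit <- function(object, newdata, ...) {
  call_cohort(newdata, object$panels)
}

#' Plot panel diagnostics of a fitted model
#'
#' Histogram of partner CVs with panel-size distribution in the margin text;
#' a quick check that panels picked low-variability references.
#'
#' @param x a `reo_fit`.
#' @param ... passed to [graphics::hist()].
#' @export
plot.reo_fit <- function(x, ...) {
  if (!nrow(x$panels)) {
    plot.new(); title(main = "reo_fit: no panels"); return(invisible(x))
  }
  graphics::hist(x$panels$partner_cv, breaks = 30,
                 main = "Partner coefficient of variation",
                 xlab = "CV over training samples", ...)
  invisible(x)
}

#' Write fitted panels as the portable trained artifact (TSV)
#'
#' Columns: target, direction, partner, partner_cv, stable_low, stable_high,
#' p, q.  The file suffices to call new patients without the training data.
#'
#' @param fit a `reo_fit` or a panel data.frame.
#' @param path output path.
#' @export
write_panels <- function(fit, path) {
  panels <- if (inherits(fit, "reo_fit")) fit$panels else fit
  write.table(panels, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a panel TSV written by [write_panels()]
#' @param path panel file path.
#' @return panel data.frame usable with [call_cohort()].
#' @export
read_panels <- function(path) {
  p <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("target", "direction", "partner", "partner_cv")
  if (!all(need %in% names(p))) stop("panel file needs columns ", paste(need, collapse = ", "))
  p
}
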
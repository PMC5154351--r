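# Evaluation protocols: paired-sample precision against tumor-minus-normal
# gold standards, and the spike-in simulation with per-miRNA sensitivity,
# specificity and F-score.

#' Gold-standard deregulation directions from paired samples
#'
#' For each tumor sample with a matched normal: a miRNA's gold-standard
#' direction is up if its tumor value exceeds the matched normal value, down
#' if smaller, indeterminate (0) on exact ties.
#'
#' @param tumors,normals expression matrices sharing features.
#' @param annotation data.frame with `sample_id`, `condition`,
#'   `paired_partner` (see [read_sample_annotation()]).
#' @return integer matrix miRNA x tumor-sample over +1 / -1 / 0.
#' @export
gold_standard_directions <- function(tumors, normals, annotation) {
  annotation <- validate_annotation(annotation)
  tum <- colnames(tumors)
  idx <- match(tum, annotation$sample_id)
  if (anyNA(idx)) stop("tumor samples missing from annotation: ",
                       paste(tum[is.na(idx)], collapse = ", "))
  partner <- annotation$paired_partner[idx]
  if (anyNA(partner)) stop("unpaired tumor samples: ", paste(tum[is.na(partner)], collapse = ", "))
  missing <- setdiff(partner, colnames(normals))
  if (length(missing)) stop("normal matrix lacks paired samples: ", paste(missing, collapse = ", "))
  feats <- intersect(rownames(tumors), rownames(normals))
  gs <- sign(tumors[feats, , drop = FALSE] - normals[feats, partner, drop = FALSE])
  storage.mode(gs) <- "integer"
  colnames(gs) <- tum
  gs
}

#' Precision report against a paired gold standard
#'
#' A call on a cell whose gold standard agrees in sign is a true positive;
#' an opposite sign is a false positive; calls on indeterminate gold cells
#' are excluded; uncalled cells are never counted.  Precision is
#' TP/(TP+FP).  The macro figures pool TP and TP+FP over the units (samples
#' or miRNAs) that made at least one call, so that
#' `macro = mean(TP)/mean(TP+FP)` over those units.
#'
#' @param calls `reo_calls` object.
#' @param gold gold-standard matrix from [gold_standard_directions()].
#' @return list of class `precision_report` with `per_sample`, `per_mirna`
#'   data.frames, the macro precisions, and mean call counts.
#' @export
precision_report <- function(calls, gold) {
  feats <- intersect(rownames(calls$calls), rownames(gold))
  samps <- intersect(colnames(calls$calls), colnames(gold))
  cm <- calls$calls[feats, samps, drop = FALSE]
  gm <- gold[feats, samps, drop = FALSE]
  tp <- (cm != 0L) & (cm == gm)
  fp <- (cm != 0L) & (gm != 0L) & (cm == -gm)
  per_unit <- function(margin) {
    tps <- apply(tp, margin, sum); fps <- apply(fp, margin, sum)
    data.frame(id = if (margin == 1) feats else samps, TP = tps, FP = fps,
               precision = ifelse(tps + fps > 0, tps / (tps + fps), NA_real_),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  per_mirna <- per_unit(1); per_sample <- per_unit(2)
  macro <- function(df) {
    used <- df$TP + df$FP > 0
    if (!any(used)) return(NA_real_)
    sum(df$TP[used]) / sum(df$TP[used] + df$FP[used])
  }
  structure(list(
    per_sample = per_sample, per_mirna = per_mirna,
    macro_sample_precision = macro(per_sample),
    macro_mirna_precision = macro(per_mirna),
    mean_calls_per_sample = mean(colSums(cm != 0L)),
    mean_samples_per_mirna = mean(rowSums(cm != 0L))),
    class = "precision_report")
}

#' @export
print.precision_report <- function(x, ...) {
  cat("Paired-sample precision report\n")
  cat(sprintf("  per-miRNA precision:  %.2f%%\n", 100 * x$macro_mirna_precision))
  cat(sprintf("  per-sample precision: %.2f%%\n", 100 * x$macro_sample_precision))
  cat(sprintf("  mean calls/sample: %.2f, mean samples/miRNA: %.2f\n",
              x$mean_calls_per_sample, x$mean_samples_per_mirna))
  invisible(x)
}

#' Positive predictive value from aggregate counts
#'
#' The precision arithmetic used throughout the reports: TP / (TP + FP).
#' Accepts the aggregate (possibly averaged, hence fractional) counts.
#'
#' @param tp true positives (or their mean over units).
#' @param fp false positives (or their mean).
#' @return TP / (TP + FP).
#' @export
ppv <- function(tp, fp) tp / (tp + fp)
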
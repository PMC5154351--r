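# Spike-in simulation: planted-truth designs on a normal backbone, spike
# application (+/- the per-miRNA maximum absolute value), scoring, and the
# replicated end-to-end protocol.

# Balanced per-column quotas summing to `total` over `m` columns, each within
# +/-1 of total/m; which columns get the extra unit is randomized.
balanced_quotas <- function(total, m) {
  base <- total %/% m
  rem <- total - base * m
  q <- rep(base, m)
  if (rem > 0) q[sample.int(m, rem)] <- base + 1L
  q
}

# Randomized bipartite assignment: each of `n_rows` rows selects `per_row`
# distinct columns; column totals follow `quotas` exactly.  Greedy
# largest-remaining-quota selection (random tie-breaking) realizes any
# feasible quota sequence.
assign_incidence <- function(n_rows, per_row, quotas) {
  m <- length(quotas)
  if (per_row > m) stop("per-row count exceeds number of columns")
  inc <- matrix(FALSE, n_rows, m)
  rem <- as.integer(quotas)
  for (r in sample.int(n_rows)) {
    ord <- order(rem + runif(m), decreasing = TRUE)  # random tie-break
    pick <- ord[seq_len(per_row)]
    if (any(rem[pick] <= 0)) stop("infeasible spike design: quota exhausted")
    inc[r, pick] <- TRUE
    rem[pick] <- rem[pick] - 1L
  }
  inc
}

#' Randomized spike-in design on an expression backbone
#'
#' Each disease sample receives exactly `up_per_sample` up-spikes and
#' `down_per_sample` down-spikes.  Each miRNA is spiked in `per_mirna_count`
#' samples up to a +/-1 balancing tolerance (when the per-sample and
#' per-miRNA margins are arithmetically inconsistent, the per-sample counts
#' win and per-miRNA totals are balanced to floor/ceil of the implied mean).
#' Spike direction is constant per miRNA: miRNAs are split into an up pool
#' and a down pool proportional to the per-sample counts, so that each
#' miRNA's planted deregulation has a single direction (a requirement for a
#' direction-specific caller to be able to score sensitivity).
#' The spike magnitude of a miRNA is the maximum absolute expression value of
#' that miRNA in the backbone.
#'
#' @param backbone expression matrix (miRNA x sample) of the samples to be
#'   turned into disease samples.
#' @param up_per_sample,down_per_sample spikes per disease sample
#'   (defaults 40 and 10).
#' @param per_mirna_count target number of spiked samples per spiked miRNA
#'   (default 14).
#' @param seed integer seed; the design is reproducible given the seed.
#' @param spiked_mirnas which miRNAs receive spikes: `NULL` (all rows, the
#'   default), an integer count (that many drawn at random, preferring
#'   miRNAs with reference headroom), or a character vector of ids.  The
#'   remaining miRNAs are profiled but never spiked, mirroring studies where
#'   only the callable subset of a profile is perturbed while the rest
#'   supplies stable reference partners.
#' @return object of class `spike_design`: list with `incidence` (sample x
#'   miRNA integer matrix over +1/-1/0), `magnitudes`, the margins and the
#'   seed.
#' @export
make_spike_design <- function(backbone, up_per_sample = 40, down_per_sample = 10,
                              per_mirna_count = 14, seed, spiked_mirnas = NULL) {
  n_s <- ncol(backbone); n_m <- nrow(backbone)
  r <- up_per_sample + down_per_sample
  total <- n_s * r
  med <- apply(backbone, 1, median)
  # a spike is only detectable when reference partners exist on the far side
  # of the shift: up spikes need miRNAs above the target, down spikes below
  elig_up <- which(vapply(med, function(b) sum(med > b + 1.5) >= 3, logical(1)))
  elig_down <- which(vapply(med, function(b) sum(med < b - 1.5) >= 3, logical(1)))
  with_seed(seed, {
    spiked <- if (is.null(spiked_mirnas)) seq_len(n_m)
      else if (is.character(spiked_mirnas)) match(spiked_mirnas, rownames(backbone))
      else {
        both <- intersect(elig_up, elig_down)
        if (length(both) >= spiked_mirnas) sort(sample(both, spiked_mirnas))
        else sort(c(both, sample(setdiff(seq_len(n_m), both), spiked_mirnas - length(both))))
      }
    if (anyNA(spiked)) stop("spiked_mirnas refers to unknown feature ids")
    n_sp <- length(spiked)
    if (total > n_sp * per_mirna_count)
      stop(sprintf(paste0("infeasible design: %d spiked cells requested but ",
                          "%d spiked miRNAs x per-miRNA count %d allows at most %d"),
                   total, n_sp, per_mirna_count, n_sp * per_mirna_count))
    n_up_pool <- round(n_sp * up_per_sample / r)
    n_down_pool <- n_sp - n_up_pool
    forced_down <- setdiff(spiked, elig_up)
    if (length(forced_down) > n_down_pool)
      stop("too many spiked miRNAs lack upward reference headroom for the up pool")
    free_down <- setdiff(intersect(spiked, elig_down), forced_down)
    if (length(forced_down) + length(free_down) < n_down_pool)
      free_down <- setdiff(spiked, forced_down)
    pool_down <- sort(c(forced_down, sample(free_down, n_down_pool - length(forced_down))))
    pool_up <- sort(setdiff(spiked, pool_down))
    inc_up <- assign_incidence(n_s, up_per_sample,
                               balanced_quotas(n_s * up_per_sample, n_up_pool))
    inc_down <- assign_incidence(n_s, down_per_sample,
                                 balanced_quotas(n_s * down_per_sample, n_down_pool))
    incidence <- matrix(0L, n_s, n_m, dimnames = list(colnames(backbone), rownames(backbone)))
    incidence[, pool_up] <- incidence[, pool_up] + (inc_up) * 1L
    incidence[, pool_down] <- incidence[, pool_down] - (inc_down) * 1L
    structure(list(incidence = incidence,
                   magnitudes = apply(abs(backbone), 1, max),
                   up_per_sample = up_per_sample, down_per_sample = down_per_sample,
                   per_mirna_count = per_mirna_count, seed = seed,
                   spiked_mirnas = rownames(backbone)[spiked]),
              class = "spike_design")
  })
}

#' Apply a spike-in design to its backbone
#'
#' Up cells gain the miRNA's magnitude, down cells lose it, all other cells
#' are untouched.  Values may become negative; rank comparisons remain
#' defined.  `clamp = TRUE` clamps at zero for raw-count realism.
#'
#' @param backbone the expression matrix the design was made from.
#' @param design a `spike_design`.
#' @param clamp clamp post-spike values at zero (default FALSE).
#' @return spiked expression matrix.
#' @export
apply_spikes <- function(backbone, design, clamp = FALSE) {
  inc <- t(design$incidence)  # miRNA x sample
  stopifnot(identical(rownames(inc), rownames(backbone)))
  out <- backbone + inc * design$magnitudes[rownames(backbone)]
  if (clamp) out[out < 0] <- 0
  attr(out, "scale") <- expr_scale(backbone)
  out
}

#' Score individual calls against a spike-in design
#'
#' Per miRNA: sensitivity over its spiked samples (a call counts only when
#' its direction matches the spike), specificity over its unspiked samples
#' (correct means no call), F = 2*Se*Sp/(Se+Sp) (0 when both are 0).  miRNAs
#' never spiked have undefined Se and are excluded from the Se average.
#'
#' @param calls `reo_calls` on the spiked cohort.
#' @param design the `spike_design` that generated it.
#' @return list of class `simulation_report` with `per_mirna` data.frame and
#'   averages `Se_bar`, `Sp_bar`, `F_bar`.
#' @export
evaluate_calls_against_design <- function(calls, design) {
  truth <- t(design$incidence)  # miRNA x sample
  feats <- rownames(truth)
  samps <- colnames(truth)
  cm <- matrix(0L, length(feats), length(samps), dimnames = list(feats, samps))
  shared <- intersect(feats, rownames(calls$calls))
  cm[shared, ] <- calls$calls[shared, samps, drop = FALSE]
  spiked <- truth != 0L
  hit <- spiked & (cm == truth)
  n_spiked <- rowSums(spiked)
  n_clean <- ncol(truth) - n_spiked
  se <- ifelse(n_spiked > 0, rowSums(hit) / n_spiked, NA_real_)
  sp <- rowSums(!spiked & cm == 0L) / n_clean
  f <- ifelse(!is.na(se) & se + sp > 0, 2 * se * sp / (se + sp), 0)
  per <- data.frame(mirna = feats, n_spiked = n_spiked, Se = se, Sp = sp, F = f,
                    stringsAsFactors = FALSE, row.names = NULL)
  # averages cover the spiked miRNAs (Se is undefined for the others, and the
  # protocol's summary figures describe the perturbed set)
  in_scope <- if (any(n_spiked > 0)) n_spiked > 0 else rep(TRUE, length(feats))
  structure(list(per_mirna = per,
                 Se_bar = mean(se[in_scope]), Sp_bar = mean(sp[in_scope]),
                 F_bar = mean(f[in_scope])),
            class = "simulation_report")
}

#' @export
print.simulation_report <- function(x, ...) {
  cat("Spike-in simulation report\n")
  cat(sprintf("  mean sensitivity: %.4f\n", x$Se_bar))
  cat(sprintf("  mean specificity: %.4f\n", x$Sp_bar))
  cat(sprintf("  mean F-score:     %.4f\n", x$F_bar))
  if (!is.null(x$replicates)) cat("  replicates: ", x$replicates, "\n", sep = "")
  invisible(x)
}

#' Replicated spike-in simulation of the full pipeline
#'
#' Per replicate: draw a fresh design, spike the backbone into a disease
#' cohort, re-run the complete training work-flow (stable pairs on the
#' untouched normals, reversal pairs against the spiked cohort, directions,
#' panels), call the spiked cohort, and score against the design.  Per-miRNA
#' Se/Sp/F are averaged across replicates.
#'
#' @param normals normal backbone expression matrix (also the training
#'   normal cohort).
#' @param up_per_sample,down_per_sample,per_mirna_count design margins, see
#'   [make_spike_design()].
#' @param replicates number of simulation replicates (default 20).
#' @param seed integer seed; replicate r uses `seed + r`.
#' @param spiked_mirnas see [make_spike_design()].
#' @param ... passed to [reo_fit()] (`stability`, `fdr`, `k`, ...).
#' @return `simulation_report` with averages across replicates, plus the
#'   per-replicate summary table in `$per_replicate`.
#' @export
run_spike_simulation <- function(normals, up_per_sample = 40, down_per_sample = 10,
                                 per_mirna_count = 14, replicates = 20, seed = 1,
                                 spiked_mirnas = NULL, ...) {
  acc <- NULL
  per_rep <- data.frame(replicate = integer(0), Se = numeric(0), Sp = numeric(0),
                        F = numeric(0))
  for (r in seq_len(replicates)) {
    design <- make_spike_design(normals, up_per_sample, down_per_sample,
                                per_mirna_count, seed = seed + r,
                                spiked_mirnas = spiked_mirnas)
    diseased <- apply_spikes(normals, design)
    fit <- reo_fit(normals, diseased, ...)
    rep_eval <- evaluate_calls_against_design(predict(fit, diseased), design)
    per_rep <- rbind(per_rep, data.frame(replicate = r, Se = rep_eval$Se_bar,
                                         Sp = rep_eval$Sp_bar, F = rep_eval$F_bar))
    pm <- rep_eval$per_mirna[c("Se", "Sp", "F")]
    acc <- if (is.null(acc)) pm else acc + pm
  }
  per <- acc / replicates
  per$mirna <- rownames(normals)
  structure(list(per_mirna = per[c("mirna", "Se", "Sp", "F")],
                 per_replicate = per_rep,
                 Se_bar = mean(per_rep$Se), Sp_bar = mean(per_rep$Sp),
                 F_bar = mean(per_rep$F), replicates = replicates),
            class = "simulation_report")
}

#' Write a simulation report as TSV (per-miRNA rows plus a summary row)
#' @param report `simulation_report`.
#' @param path output path.
#' @export
write_simulation_report <- function(report, path) {
  df <- report$per_mirna
  avg <- df[1, , drop = FALSE]
  avg[1, ] <- NA
  avg$mirna <- "AVERAGE"
  avg$Se <- report$Se_bar; avg$Sp <- report$Sp_bar; avg$F <- report$F_bar
  write.table(rbind(df, avg), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
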
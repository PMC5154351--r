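# Downstream analyses driven by the individual call matrix: subtype
# enrichment, the four-stage mutually exclusive miRNA-target screen against
# copy-number alterations, and survival grouping.

#' Subtype-specific deregulation enrichment
#'
#' For each (miRNA, direction, subtype): N = samples with a subtype label and
#' call data, K = subtype size, n = samples carrying that call for the
#' miRNA, k = overlap; upper-tail hypergeometric p.  Up- and down-calls are
#' tested separately; miRNA/direction combinations with no calls are
#' skipped.
#'
#' @param calls `reo_calls` object.
#' @param annotation annotation data.frame with `sample_id` and `subtype`.
#' @param alpha significance flag cutoff (default 0.05).
#' @return data.frame with counts, `p` and `significant`.
#' @export
subtype_enrichment <- function(calls, annotation, alpha = 0.05) {
  ann <- annotation[!is.na(annotation$subtype), , drop = FALSE]
  samples <- intersect(colnames(calls$calls), ann$sample_id)
  if (!length(samples)) stop("no samples with both calls and subtype labels")
  subtype <- setNames(ann$subtype, ann$sample_id)[samples]
  N <- length(samples)
  cm <- calls$calls[, samples, drop = FALSE]
  out <- list()
  for (sub in unique(subtype)) {
    K <- sum(subtype == sub)
    for (dir in c("up", "down")) {
      val <- if (dir == "up") 1L else -1L
      carr <- cm == val
      n_vec <- rowSums(carr)
      k_vec <- rowSums(carr[, subtype == sub, drop = FALSE])
      use <- n_vec > 0
      if (!any(use)) next
      p <- mapply(function(n, k) hypergeom_tail(N, K, n, k, "upper"),
                  n_vec[use], k_vec[use])
      out[[paste(sub, dir)]] <- data.frame(
        mirna = rownames(cm)[use], direction = dir, subtype = sub,
        N = N, K = K, n = n_vec[use], k = k_vec[use], p = p,
        significant = p < alpha, stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(mirna = character(0), direction = character(0), subtype = character(0),
               N = integer(0), K = integer(0), n = integer(0), k = integer(0),
               p = numeric(0), significant = logical(0))
  rownames(res) <- NULL
  res[order(res$p), , drop = FALSE]
}

#' Mutual-exclusivity test for two event sample sets
#'
#' Lower-tail hypergeometric probability of observing at most the actual
#' overlap between two sample sets drawn from a common universe: small p
#' means the events co-occur less than chance predicts.
#'
#' @param set_a,set_b character vectors of sample ids (subsets of universe).
#' @param universe character vector of all eligible sample ids.
#' @return lower-tail p-value.
#' @export
exclusivity_test <- function(set_a, set_b, universe) {
  if (!length(universe)) stop("empty universe")
  set_a <- intersect(set_a, universe); set_b <- intersect(set_b, universe)
  hypergeom_tail(length(universe), length(set_a), length(set_b),
                 length(intersect(set_a, set_b)), tail = "lower")
}

#' Direction compatibility of a miRNA call and a target CNA type
#'
#' Coordinated loss/gain: miRNA up with target deletion, or miRNA down with
#' target amplification.
#'
#' @param mirna_dir `"up"` or `"down"`.
#' @param cna_type `"AMP"`, `"DEL"` (or `"amplified"`/`"deleted"`).
#' @return logical.
#' @export
direction_compatible <- function(mirna_dir, cna_type) {
  cna <- toupper(substr(cna_type, 1, 3))
  (mirna_dir == "up" & cna == "DEL") | (mirna_dir == "down" & cna == "AMP")
}

#' Target-expression consistency of an exclusive pair
#'
#' The target gene must shift in the expected direction in BOTH event groups
#' relative to the normal cohort: the samples only carrying the miRNA event
#' and the samples only carrying the CNA (one-sided t-tests at `P < alpha`).
#' Samples carrying both events must be excluded by the caller ("only with"
#' semantics).
#'
#' @param mrna gene x sample expression matrix (tumors and normals).
#' @param mirna_only,cna_only,normal disjoint sample-id sets.
#' @param gene gene id.
#' @param expected expected target shift, `"up"` or `"down"`.
#' @param alpha per-test cutoff (default 0.05).
#' @return list with `pass`, `p_mirna`, `p_cna` and a `reason` when failing
#'   on group size.
#' @export
target_consistency <- function(mrna, mirna_only, cna_only, normal, gene,
                               expected = c("down", "up"), alpha = 0.05) {
  expected <- match.arg(expected)
  if (length(intersect(mirna_only, cna_only)))
    stop("event groups must be disjoint ('only with' semantics)")
  if (length(mirna_only) < 2 || length(cna_only) < 2 || length(normal) < 2)
    return(list(pass = FALSE, p_mirna = NA_real_, p_cna = NA_real_,
                reason = "group with < 2 samples"))
  side <- if (expected == "down") "less" else "greater"
  p_m <- welch_t(mrna[gene, mirna_only], mrna[gene, normal], alternative = side)$p
  p_c <- welch_t(mrna[gene, cna_only], mrna[gene, normal], alternative = side)$p
  list(pass = p_m < alpha && p_c < alpha, p_mirna = p_m, p_cna = p_c, reason = NA_character_)
}

# Vectorised per-gene Welch t over rows of a matrix: group vs normal,
# two-sided.  Used by deg_detect; one gene is cross-checked against
# stats::t.test in the test suite.
row_welch_p <- function(mrna, group, normal) {
  row_welch_p2(mrna[, group, drop = FALSE], mrna[, normal, drop = FALSE])
}

row_welch_p2 <- function(x, y) {
  nx <- ncol(x); ny <- ncol(y)
  mx <- rowMeans(x); my <- rowMeans(y)
  vx <- rowSums((x - mx)^2) / (nx - 1); vy <- rowSums((y - my)^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  t <- (mx - my) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- 2 * pt(abs(t), df, lower.tail = FALSE)
  p[se2 == 0] <- ifelse(mx[se2 == 0] == my[se2 == 0], 1, 0)
  p
}

#' Differentially expressed genes between a sample group and normals
#'
#' Per-gene two-sided Welch t-test, BH correction across all genes tested,
#' genes with q < `fdr` reported.
#'
#' @param mrna gene x sample expression matrix.
#' @param group,normal sample-id sets (each >= 2).
#' @param fdr FDR cutoff (default 0.05).
#' @return character vector of DEG ids.
#' @export
deg_detect <- function(mrna, group, normal, fdr = 0.05) {
  if (length(group) < 2 || length(normal) < 2) stop("both groups need >= 2 samples")
  p <- row_welch_p(mrna, group, normal)
  q <- bh_adjust(p)
  rownames(mrna)[q < fdr]
}

#' Pathway enrichment of a gene list (hypergeometric, raw p)
#'
#' Upper-tail hypergeometric per pathway on the measured universe; pathways
#' with p < `alpha` are reported (no multiplicity correction, matching the
#' screening protocol).
#'
#' @param genes character vector of genes (will be intersected with universe).
#' @param sets `gene_sets` collection.
#' @param universe measured gene universe (intersected with the collection's).
#' @param alpha cutoff (default 0.05).
#' @return data.frame of enriched pathways with counts and `p`, ordered by p.
#' @export
pathway_enrichment <- function(genes, sets, universe = sets$universe, alpha = 0.05) {
  uni <- intersect(sets$universe, universe)
  genes <- intersect(genes, uni)
  if (!length(genes))
    return(data.frame(pathway = character(0), N = integer(0), K = integer(0),
                      n = integer(0), k = integer(0), p = numeric(0)))
  N <- length(uni); n <- length(genes)
  res <- lapply(names(sets$sets), function(nm) {
    pset <- intersect(sets$sets[[nm]], uni)
    k <- length(intersect(genes, pset))
    data.frame(pathway = nm, N = N, K = length(pset), n = n, k = k,
               p = if (length(pset)) hypergeom_tail(N, length(pset), n, k, "upper") else 1,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res <- res[res$p < alpha, , drop = FALSE]
  res[order(res$p), , drop = FALSE]
}

#' Significance of the overlap between two pathway lists
#'
#' Upper-tail hypergeometric with N = catalogue size, K and n the two list
#' sizes, k their overlap.
#'
#' @param list_a,list_b character vectors of pathway names.
#' @param total_pathways catalogue size the lists were drawn from.
#' @return upper-tail p-value.
#' @export
pathway_overlap_test <- function(list_a, list_b, total_pathways) {
  k <- length(intersect(list_a, list_b))
  hypergeom_tail(total_pathways, length(unique(list_a)), length(unique(list_b)), k, "upper")
}

#' Four-stage screen for mutually exclusive miRNA-target pairs
#'
#' For every interacting (miRNA, gene) with a direction-compatible pairing
#' (miRNA up / target deleted, or miRNA down / target amplified):
#' stage 1 tests mutual exclusivity of the two patient sets (lower-tail
#' hypergeometric); stage 2 tests target-expression consistency in both
#' "only with" groups versus normals; stage 3 derives the two DEG lists and
#' their enriched pathways; stage 4 tests the overlap of the two pathway
#' lists.  The verdict is true iff all four stages pass.  Stages after the
#' first failure are not computed (recorded as NA).
#'
#' @param calls `reo_calls` on the tumor cohort.
#' @param cna `cn_calls` matrix (genes x tumor samples).
#' @param ix interaction data.frame (pre-filtered to >= 2 sources).
#' @param mrna gene x sample expression matrix covering tumors and normals.
#' @param normal_samples character vector of normal sample ids in `mrna`.
#' @param sets `gene_sets` collection for stages 3-4.
#' @param thresholds named list: `exclusivity_alpha`, `consistency_alpha`,
#'   `deg_fdr`, `pathway_alpha`, `overlap_alpha` (all default 0.05).
#' @return data.frame with one row per (miRNA, gene, pairing): event-set
#'   sizes, per-stage p-values/passes and the final `verdict`.
#' @export
find_exclusive_pairs <- function(calls, cna, ix, mrna, normal_samples, sets,
                                 thresholds = list()) {
  th <- modifyList(list(exclusivity_alpha = 0.05, consistency_alpha = 0.05,
                        deg_fdr = 0.05, pathway_alpha = 0.05, overlap_alpha = 0.05),
                   thresholds)
  universe <- intersect(colnames(calls$calls), colnames(cna))
  if (!length(universe)) stop("no samples shared between calls and copy-number data")
  total_pathways <- length(sets$sets)
  rows <- list()
  for (i in seq_len(nrow(ix))) {
    m <- ix$mirna_id[i]; g <- ix$gene_id[i]
    if (!(m %in% rownames(calls$calls)) || !(g %in% rownames(cna)) ||
        !(g %in% rownames(mrna))) next
    for (pairing in c("up_del", "down_amp")) {
      mdir <- if (pairing == "up_del") "up" else "down"
      ctype <- if (pairing == "up_del") "DEL" else "AMP"
      mset <- universe[calls$calls[m, universe] == (if (mdir == "up") 1L else -1L)]
      cset <- universe[cna[g, universe] == ctype]
      if (!length(mset) || !length(cset)) next
      row <- list(mirna_id = m, gene_id = g, pairing = pairing,
                  n_mirna = length(mset), n_cna = length(cset),
                  overlap = length(intersect(mset, cset)), universe = length(universe),
                  exclusivity_p = NA_real_, consistency_p_mirna = NA_real_,
                  consistency_p_cna = NA_real_, n_pathways_mirna = NA_integer_,
                  n_pathways_cna = NA_integer_, pathway_overlap = NA_integer_,
                  overlap_p = NA_real_, stage1 = NA, stage2 = NA, stage3 = NA,
                  stage4 = NA, verdict = FALSE)
      row$exclusivity_p <- exclusivity_test(mset, cset, universe)
      row$stage1 <- row$exclusivity_p < th$exclusivity_alpha
      if (row$stage1) {
        m_only <- setdiff(mset, cset); c_only <- setdiff(cset, mset)
        expected <- if (pairing == "up_del") "down" else "up"
        cons <- target_consistency(mrna, m_only, c_only, normal_samples, g,
                                   expected, th$consistency_alpha)
        row$consistency_p_mirna <- cons$p_mirna
        row$consistency_p_cna <- cons$p_cna
        row$stage2 <- isTRUE(cons$pass)
        if (row$stage2) {
          measured <- rownames(mrna)
          degs_m <- deg_detect(mrna, m_only, normal_samples, th$deg_fdr)
          degs_c <- deg_detect(mrna, c_only, normal_samples, th$deg_fdr)
          pw_m <- pathway_enrichment(degs_m, sets, measured, th$pathway_alpha)$pathway
          pw_c <- pathway_enrichment(degs_c, sets, measured, th$pathway_alpha)$pathway
          row$n_pathways_mirna <- length(pw_m)
          row$n_pathways_cna <- length(pw_c)
          row$stage3 <- length(pw_m) > 0 && length(pw_c) > 0
          if (row$stage3) {
            row$pathway_overlap <- length(intersect(pw_m, pw_c))
            row$overlap_p <- pathway_overlap_test(pw_m, pw_c, total_pathways)
            row$stage4 <- row$overlap_p < th$overlap_alpha
            row$verdict <- isTRUE(row$stage4)
          }
        }
      }
      rows[[length(rows) + 1L]] <- as.data.frame(row, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(mirna_id = character(0), gene_id = character(0),
                      pairing = character(0), verdict = logical(0)))
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Survival grouping by individual deregulation of one miRNA
#'
#' Splits patients into "deregulated" (a call for the miRNA — matching
#' `direction` when given) versus "others" and applies the log-rank test.
#'
#' @param calls `reo_calls` object.
#' @param annotation annotation with `sample_id`, `survival_time`, `event`.
#' @param mirna_id miRNA to group by.
#' @param direction optional `"up"` or `"down"` filter on the call.
#' @return list of class `survival_grouping` with `labels` (named character),
#'   `logrank_p`, `statistic` and group sizes; `logrank_p` is NA with a
#'   reason when a group is empty.
#' @export
survival_grouping <- function(calls, annotation, mirna_id, direction = NULL) {
  if (!(mirna_id %in% rownames(calls$calls))) stop("no panel calls for ", mirna_id)
  ann <- annotation[!is.na(annotation$survival_time) & !is.na(annotation$event), , drop = FALSE]
  samples <- intersect(colnames(calls$calls), ann$sample_id)
  if (!length(samples)) stop("no samples with both calls and survival data")
  cvec <- calls$calls[mirna_id, samples]
  dereg <- if (is.null(direction)) cvec != 0L
           else cvec == (if (direction == "up") 1L else -1L)
  labels <- setNames(ifelse(dereg, "deregulated", "others"), samples)
  idx <- match(samples, ann$sample_id)
  out <- list(mirna_id = mirna_id, labels = labels,
              n_deregulated = sum(dereg), n_others = sum(!dereg),
              logrank_p = NA_real_, statistic = NA_real_, reason = NA_character_)
  if (out$n_deregulated == 0 || out$n_others == 0) {
    out$reason <- "a group is empty"
  } else {
    lr <- logrank(ann$survival_time[idx], ann$event[idx], labels)
    out$logrank_p <- lr$p
    out$statistic <- lr$statistic
  }
  class(out) <- "survival_grouping"
  out
}

#' @export
print.survival_grouping <- function(x, ...) {
  cat("Survival grouping for ", x$mirna_id, ": ", x$n_deregulated,
      " deregulated vs ", x$n_others, " others\n", sep = "")
  if (is.na(x$logrank_p)) cat("  log-rank p: not computed (", x$reason, ")\n", sep = "")
  else cat(sprintf("  log-rank chi-square = %.3f, p = %.3g\n", x$statistic, x$logrank_p))
  invisible(x)
}
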
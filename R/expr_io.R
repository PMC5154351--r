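# Readers, writers and preprocessing for the tabular formats the pipeline
# touches: expression TSV, GMT gene sets, interaction tables, copy-number
# log2 ratios and sample annotations.

#' Construct an expression matrix
#'
#' A plain numeric matrix (features in rows, samples in columns) carrying a
#' `scale` attribute (`"raw"` or `"log2"`).  All rank comparisons in the
#' package operate on such matrices; missing values are rejected because
#' within-sample orderings are undefined for them.
#'
#' @param values numeric matrix with unique rownames (feature ids) and unique
#'   colnames (sample ids).
#' @param scale `"raw"` (non-negative) or `"log2"`.
#' @return the matrix with attribute `scale` set.
#' @export
expression_matrix <- function(values, scale = c("log2", "raw")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("expression values must be numeric")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs feature rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids")
  if (anyNA(values)) stop("missing expression cells are not supported; impute upstream")
  if (scale == "raw" && any(values < 0))
    stop("raw-scale expression values must be non-negative")
  attr(values, "scale") <- scale
  values
}

expr_scale <- function(m) attr(m, "scale") %||% "log2"

#' Read an expression matrix from TSV
#'
#' First column holds feature ids, header row holds sample ids.  Set
#' `orientation = "samples"` for dialects with samples in rows; the matrix is
#' transposed on load so features are always in rows.
#'
#' @param path file path.
#' @param orientation `"features"` (rows are features, default) or `"samples"`.
#' @param scale scale tag to record, see [expression_matrix()].
#' @return an expression matrix.
#' @export
read_expression_matrix <- function(path, orientation = c("features", "samples"),
                                   scale = c("log2", "raw")) {
  orientation <- match.arg(orientation)
  raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character")
  if (ncol(raw) < 2) stop("expression TSV needs an id column and >=1 sample column")
  ids <- raw[[1]]
  if (anyDuplicated(ids))
    stop("duplicate feature ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  body <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(body), dim = dim(body), dimnames = dimnames(body)))
  bad <- which(is.na(num) & !is.na(body) & nzchar(trimws(body)), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric cell at row %d ('%s'), column '%s'",
                 bad[1, 1], ids[bad[1, 1]], colnames(body)[bad[1, 2]]))
  }
  rownames(num) <- ids
  m <- expression_matrix(num, scale = match.arg(scale))
  if (orientation == "samples") m <- expression_matrix(t(m), scale = expr_scale(m))
  m
}

#' Write an expression matrix to TSV
#'
#' @param m expression matrix.
#' @param path output path.
#' @param id_header header for the feature-id column.
#' @export
write_expression_matrix <- function(m, path, id_header = "feature_id") {
  df <- data.frame(id = rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_header
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Quantile normalize an expression matrix
#'
#' Every column is mapped onto the common reference distribution (the row-wise
#' mean of the per-column sorted values).  Tied values within a column receive
#' the mean of the reference values they span.
#'
#' @param m expression matrix (>= 2 samples).
#' @return normalized matrix, same dimnames and scale tag.
#' @export
quantile_normalize <- function(m) {
  if (ncol(m) < 2) {
    warning("quantile normalization of a single-sample matrix is a no-op")
    return(m)
  }
  ref <- rowMeans(apply(m, 2, sort))
  out <- apply(m, 2, function(x) {
    s <- ref[rank(x, ties.method = "first")]
    ave(s, match(x, x), FUN = mean)
  })
  dimnames(out) <- dimnames(m)
  attr(out, "scale") <- expr_scale(m)
  out
}

#' Log2 transform a raw-scale matrix
#'
#' @param m raw-scale expression matrix.
#' @param offset pseudocount added before taking logs (default 1).
#' @return log2-scale matrix.
#' @export
log2_transform <- function(m, offset = 1) {
  if (expr_scale(m) == "log2") stop("matrix is already on the log2 scale")
  if (offset <= 0) stop("offset must be positive")
  out <- log2(m + offset)
  attr(out, "scale") <- "log2"
  out
}

#' Call gene-level copy-number status from log2 ratios
#'
#' Strict cutoffs: ratio > `amp_cut` is amplified, ratio < `del_cut` is
#' deleted, anything else (including the boundaries) is neutral.
#'
#' @param log2ratio gene x sample numeric matrix of log2 copy-number ratios.
#' @param amp_cut amplification cutoff (default 0.1).
#' @param del_cut deletion cutoff (default -0.1).
#' @return object of class `cn_calls`: a character matrix over
#'   `"AMP"`/`"DEL"`/`"NEUT"` with the thresholds as attributes.
#' @export
call_copy_number <- function(log2ratio, amp_cut = 0.1, del_cut = -0.1) {
  if (!(amp_cut > 0 && del_cut < 0)) stop("need amp_cut > 0 > del_cut")
  if (anyNA(log2ratio) || any(!is.finite(log2ratio))) stop("log2 ratios must be finite")
  calls <- matrix("NEUT", nrow(log2ratio), ncol(log2ratio), dimnames = dimnames(log2ratio))
  calls[log2ratio > amp_cut] <- "AMP"
  calls[log2ratio < del_cut] <- "DEL"
  structure(calls, amp_cut = amp_cut, del_cut = del_cut, class = c("cn_calls", class(calls)))
}

#' Keep genes whose copy-number calls agree with their expression
#'
#' A gene is retained iff every alteration class it exhibits (with >= 2
#' samples) shifts expression in the concordant direction relative to the
#' neutral samples: amplified higher, deleted lower, one-sided Welch t-test at
#' `P < alpha`.  Genes that are neutral everywhere, or that lack 2 samples in
#' a required group, are dropped.
#'
#' @param cna `cn_calls` matrix from [call_copy_number()].
#' @param mrna gene x sample expression matrix sharing sample ids with `cna`.
#' @param alpha significance cutoff (default 0.05).
#' @return character vector of retained gene ids.
#' @export
filter_cna_expression_consistent <- function(cna, mrna, alpha = 0.05) {
  samples <- intersect(colnames(cna), colnames(mrna))
  if (!length(samples)) stop("no shared samples between copy-number and expression matrices")
  genes <- intersect(rownames(cna), rownames(mrna))
  keep <- character(0)
  for (g in genes) {
    st <- cna[g, samples]
    ex <- mrna[g, samples]
    neut <- ex[st == "NEUT"]
    if (length(neut) < 2) next
    classes <- intersect(c("AMP", "DEL"), unique(st))
    if (!length(classes)) next
    ok <- TRUE
    for (cl in classes) {
      alt <- ex[st == cl]
      if (length(alt) < 2) { ok <- FALSE; break }
      side <- if (cl == "AMP") "greater" else "less"
      p <- welch_t(alt, neut, alternative = side)$p
      if (!(p < alpha)) { ok <- FALSE; break }
    }
    if (ok) keep <- c(keep, g)
  }
  keep
}

#' Filter a miRNA-target interaction table by database support
#'
#' @param ix data.frame with columns `mirna_id`, `gene_id`, `source_count`.
#' @param min_sources minimum number of supporting databases (default 2).
#' @return filtered data.frame, row order preserved.
#' @export
filter_interactions <- function(ix, min_sources = 2) {
  validate_interactions(ix)
  ix[ix$source_count >= min_sources, , drop = FALSE]
}

validate_interactions <- function(ix) {
  need <- c("mirna_id", "gene_id", "source_count")
  if (!all(need %in% names(ix))) stop("interaction table needs columns ", paste(need, collapse = ", "))
  if (anyDuplicated(paste(ix$mirna_id, ix$gene_id))) stop("duplicate (mirna_id, gene_id) records")
  if (any(ix$source_count < 1)) stop("source_count must be >= 1")
  invisible(ix)
}

#' Read a miRNA-target interaction TSV
#'
#' @param path TSV with columns `mirna_id`, `gene_id`, `source_count`.
#' @return validated data.frame.
#' @export
read_interactions <- function(path) {
  ix <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  validate_interactions(ix)
  ix
}

#' Read a GMT gene-set collection
#'
#' Each line: set name, description, then member genes, tab-separated.
#'
#' @param path GMT file path.
#' @return object of class `gene_sets`: list with `sets` (named list of
#'   character vectors) and `universe` (union of all members).
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  names <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(names)) stop("duplicate gene-set names in ", path)
  sets <- lapply(parts, function(p) {
    genes <- unique(p[-(1:2)][nzchar(p[-(1:2)])])
    if (!length(p) > 2 || !length(genes)) stop("gene set '", p[[1]], "' has no members")
    genes
  })
  names(sets) <- names
  gene_sets(sets)
}

#' Build a gene-set collection from a named list
#' @param sets named list of character vectors (all non-empty).
#' @return `gene_sets` object with the universe computed.
#' @export
gene_sets <- function(sets) {
  if (is.null(names(sets)) || anyDuplicated(names(sets))) stop("sets need unique names")
  if (any(!lengths(sets))) stop("every gene set must be non-empty")
  structure(list(sets = sets, universe = unique(unlist(sets, use.names = FALSE))),
            class = "gene_sets")
}

#' Write a gene-set collection as GMT
#' @param gs `gene_sets` object.
#' @param path output path.
#' @param descriptions optional descriptions (defaults to set names).
#' @export
write_gene_sets <- function(gs, path, descriptions = names(gs$sets)) {
  lines <- mapply(function(nm, d, genes) paste(c(nm, d, genes), collapse = "\t"),
                  names(gs$sets), descriptions, gs$sets)
  writeLines(lines, path)
  invisible(path)
}

#' Read a sample annotation TSV
#'
#' Expected columns: `sample_id`, `condition` (`normal`/`tumor`); optional
#' `paired_partner`, `subtype`, `survival_time`, `event`.  Pairing must be
#' symmetric and cross conditions; an event indicator requires a survival
#' time.
#'
#' @param path TSV path.
#' @return validated data.frame.
#' @export
read_sample_annotation <- function(path) {
  ann <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    na.strings = c("NA", ""))
  validate_annotation(ann)
}

validate_annotation <- function(ann) {
  if (!all(c("sample_id", "condition") %in% names(ann)))
    stop("annotation needs sample_id and condition columns")
  if (anyDuplicated(ann$sample_id)) stop("duplicate sample ids in annotation")
  if (!all(ann$condition %in% c("normal", "tumor")))
    stop("condition must be 'normal' or 'tumor'")
  if ("paired_partner" %in% names(ann)) {
    has <- !is.na(ann$paired_partner)
    idx <- match(ann$paired_partner[has], ann$sample_id)
    if (anyNA(idx)) stop("paired_partner refers to unknown sample ids")
    back <- ann$paired_partner[idx]
    if (!isTRUE(all(back == ann$sample_id[has]))) stop("pairing is not symmetric")
    if (any(ann$condition[idx] == ann$condition[has]))
      stop("pairing must cross conditions (tumor <-> normal)")
  }
  if ("event" %in% names(ann)) {
    ev <- !is.na(ann$event)
    if (!all(ann$event[ev] %in% c(0, 1))) stop("event must be 0/1")
    if (!("survival_time" %in% names(ann)) || anyNA(ann$survival_time[ev]))
      stop("event indicator requires survival_time")
    st <- !is.na(ann$survival_time)
    if (any(ann$survival_time[st] < 0)) stop("survival_time must be non-negative")
  }
  ann
}
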
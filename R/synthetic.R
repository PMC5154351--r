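# Synthetic cohort generators: normal/tumor miRNA cohorts with stable
# orderings and heterogeneous planted deregulation, plus a linked
# mRNA/copy-number/interaction/pathway layer with one planted mutually
# exclusive miRNA-target pair.

#' Configuration for a synthetic miRNA cohort
#'
#' Baselines are spaced `baseline_spread` apart on the log2 scale, so
#' orderings between sufficiently separated miRNAs are stable in normals at
#' the chosen noise level.  Differential miRNAs are shifted by
#' `effect_size` (half up, half down) in a random `de_sample_fraction`
#' subset of tumor samples; normals are never perturbed.
#'
#' @param n_mirnas number of miRNAs (default 200).
#' @param n_normal,n_tumor cohort sizes (default 60 each).
#' @param n_de_mirnas number of differential miRNAs (default 40).
#' @param de_sample_fraction fraction of tumors carrying each miRNA's shift
#'   (default 0.5 — per-sample heterogeneity).
#' @param effect_size log2 shift of planted deregulation (default 4).
#' @param noise_sd per-cell Gaussian noise sd on the log2 scale (default 0.5;
#'   each miRNA gets its own sd drawn uniformly from 0.5x to 1.5x this value).
#' @param baseline_spread gap between adjacent baselines (default 0.05, i.e.
#'   a ~10 log2-unit dynamic range for 200 miRNAs, comparable to sequencing
#'   profiles).
#' @param seed RNG seed (default 7).
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_mirnas = 200, n_normal = 60, n_tumor = 60,
                          n_de_mirnas = 40, de_sample_fraction = 0.5,
                          effect_size = 4, noise_sd = 0.5,
                          baseline_spread = 0.05, seed = 7) {
  cfg <- list(n_mirnas = n_mirnas, n_normal = n_normal, n_tumor = n_tumor,
              n_de_mirnas = n_de_mirnas, de_sample_fraction = de_sample_fraction,
              effect_size = effect_size, noise_sd = noise_sd,
              baseline_spread = baseline_spread, seed = seed)
  stopifnot(n_mirnas > 0, n_normal > 0, n_tumor > 0, n_de_mirnas >= 0,
            n_de_mirnas <= n_mirnas, de_sample_fraction > 0, de_sample_fraction <= 1,
            noise_sd >= 0, baseline_spread > 0)
  class(cfg) <- "cohort_config"
  cfg
}

#' Generate a synthetic normal/tumor miRNA cohort with known truth
#'
#' @param cfg a [cohort_config()].
#' @param count_mode simulate negative-binomial raw counts instead of
#'   Gaussian log2 values (default FALSE).
#' @return list with `normals`, `tumors` (expression matrices), `truth`
#'   (miRNA x tumor incidence over +1/-1/0), `de_mirnas`, `directions`
#'   (named, planted group-level direction per DE miRNA), `baselines`, `cfg`.
#' @export
generate_cohort <- function(cfg = cohort_config(), count_mode = FALSE) {
  with_seed(cfg$seed, {
    ids <- sprintf("miR-%04d", seq_len(cfg$n_mirnas))
    samples_n <- sprintf("N%03d", seq_len(cfg$n_normal))
    samples_t <- sprintf("T%03d", seq_len(cfg$n_tumor))
    base <- 4 + (seq_len(cfg$n_mirnas) - 1) * cfg$baseline_spread
    names(base) <- ids
    # per-miRNA variability (0.5x-1.5x the nominal sd): real profiles mix
    # tight and noisy miRNAs, which is what the CV partner ranking exploits
    sds <- runif(cfg$n_mirnas, 0.5, 1.5) * cfg$noise_sd
    names(sds) <- ids
    draw <- function(samples) {
      m <- base + matrix(rnorm(cfg$n_mirnas * length(samples), sd = sds),
                         cfg$n_mirnas, length(samples))
      dimnames(m) <- list(ids, samples)
      m
    }
    normals <- draw(samples_n)
    tumors <- draw(samples_t)
    truth <- matrix(0L, cfg$n_mirnas, cfg$n_tumor, dimnames = list(ids, samples_t))
    # deregulation is only representable (and biologically meaningful) for
    # miRNAs with reference partners inside the shift window: an up-shifted
    # miRNA needs >= 3 miRNAs between its baseline and its shifted value
    elig_up <- which(vapply(base, function(b)
      cfg$effect_size == 0 ||
        sum(base > b + 1.5 & base < b + cfg$effect_size) >= 3, logical(1)))
    elig_down <- which(vapply(base, function(b)
      cfg$effect_size == 0 ||
        sum(base < b - 1.5 & base > b - cfg$effect_size) >= 3, logical(1)))
    n_up <- ceiling(cfg$n_de_mirnas / 2); n_down <- cfg$n_de_mirnas - n_up
    if (length(elig_up) < n_up || length(elig_down) < n_down)
      stop("effect_size/baseline_spread leave too few miRNAs with reference headroom")
    de_up <- sample(elig_up, n_up)
    de_down <- sample(setdiff(elig_down, de_up), n_down)
    de <- c(de_up, de_down)
    dirs <- rep(c(1L, -1L), c(n_up, n_down))
    ord <- order(de); de <- de[ord]; dirs <- dirs[ord]
    n_hit <- max(1L, round(cfg$de_sample_fraction * cfg$n_tumor))
    for (j in seq_along(de)) {
      hit <- sample.int(cfg$n_tumor, n_hit)
      truth[de[j], hit] <- dirs[j]
      tumors[de[j], hit] <- tumors[de[j], hit] + dirs[j] * cfg$effect_size
    }
    if (count_mode) {
      normals <- matrix(rnbinom(length(normals), mu = 2^normals, size = 10),
                        nrow(normals), ncol(normals), dimnames = dimnames(normals))
      tumors <- matrix(rnbinom(length(tumors), mu = pmax(2^tumors, 1e-3), size = 10),
                       nrow(tumors), ncol(tumors), dimnames = dimnames(tumors))
    }
    scale <- if (count_mode) "raw" else "log2"
    list(normals = expression_matrix(normals, scale),
         tumors = expression_matrix(tumors, scale),
         truth = truth,
         de_mirnas = ids[de],
         directions = setNames(ifelse(dirs == 1L, "up", "down"), ids[de]),
         baselines = base, noise_sds = sds, cfg = cfg)
  })
}

#' Closed-form expected stable-pair fraction for a synthetic cohort
#'
#' Under the Gaussian noise model, a pair of miRNAs with baseline gap g and
#' noise sds (s_i, s_j) orders correctly in one sample with probability
#' `pnorm(g / sqrt(s_i^2 + s_j^2))`; the pair is stable when the binomial
#' support count strictly exceeds `threshold * n`.  Used as an
#' order-statistics oracle for the generator.
#'
#' @param cohort result of [generate_cohort()] (baselines and per-miRNA sds
#'   are taken from it).
#' @param threshold stability threshold (default 0.95).
#' @return expected fraction of all unordered pairs that are stable.
#' @export
expected_stable_fraction <- function(cohort, threshold = 0.95) {
  n <- cohort$cfg$n_normal
  need <- floor(threshold * n) + 1      # smallest count with count/n > threshold
  gaps <- abs(outer(cohort$baselines, cohort$baselines, "-"))
  sd2 <- outer(cohort$noise_sds^2, cohort$noise_sds^2, "+")
  ut <- upper.tri(gaps)
  p_less <- pnorm(gaps[ut] / sqrt(sd2[ut]))
  # either orientation can be stable; for g > 0 only the majority one matters
  p_stable <- pbinom(need - 1, n, p_less, lower.tail = FALSE) +
    pbinom(need - 1, n, 1 - p_less, lower.tail = FALSE)
  mean(p_stable)
}

#' Generate the linked mRNA / copy-number / interaction / pathway layer
#'
#' Plants one mutually exclusive miRNA-target pair on top of a cohort from
#' [generate_cohort()]: the target gene is deleted (log2 ratio -0.5) in a
#' tumor subset disjoint from the miRNA's up-regulated subset, its expression
#' drops in both event groups, and a module of co-regulated genes places both
#' DEG lists into the same two planted pathways.  Distractor interactions are
#' constructed to fail specific stages: a target without copy-number events
#' (stage 1, vacuous), a target deleted exactly in its miRNA's deregulated
#' samples (stage 1, co-occurrence), a target whose expression ignores the
#' miRNA group (stage 2), and a target whose pathway footprint is disjoint
#' from the miRNA's (stage 4); plus a single-source record that the
#' interaction filter drops and a direction-incompatible record.
#'
#' @param cohort result of [generate_cohort()] (needs >= 2 up-regulated DE
#'   miRNAs and `de_sample_fraction <= 0.5`).
#' @param n_genes total genes in the mRNA layer (default 300).
#' @param n_normal_mrna normal mRNA samples (default the cohort's normals).
#' @param noise_sd mRNA noise sd (default 0.5).
#' @param seed RNG seed (default cohort seed + 1).
#' @return list with `mrna` (genes x (tumor+normal) expression matrix),
#'   `normal_samples`, `cna_log2` (genes x tumor), `interactions`,
#'   `sets` (`gene_sets`), `planted` (list describing the true pair) and
#'   `distractors`.
#' @export
generate_linked_omics <- function(cohort, n_genes = 300, n_normal_mrna = NULL,
                                  noise_sd = 0.5, seed = NULL) {
  seed <- seed %||% (cohort$cfg$seed + 1)
  up_mirnas <- names(cohort$directions)[cohort$directions == "up"]
  if (length(up_mirnas) < 2) stop("need >= 2 up-regulated DE miRNAs in the cohort")
  with_seed(seed, {
    tumor_ids <- colnames(cohort$tumors)
    n_t <- length(tumor_ids)
    normal_ids <- sprintf("MN%03d", seq_len(n_normal_mrna %||% ncol(cohort$normals)))
    genes <- sprintf("G%04d", seq_len(n_genes))
    base <- runif(n_genes, 6, 10)
    mrna <- base + matrix(rnorm(n_genes * (n_t + length(normal_ids)), sd = noise_sd),
                          n_genes, n_t + length(normal_ids))
    dimnames(mrna) <- list(genes, c(tumor_ids, normal_ids))
    cna <- matrix(rnorm(n_genes * n_t, sd = 0.02), n_genes, n_t,
                  dimnames = list(genes, tumor_ids))

    m_plant <- up_mirnas[1]
    s_m <- tumor_ids[cohort$truth[m_plant, ] == 1L]
    rest <- sample(setdiff(tumor_ids, s_m))
    if (length(rest) < 10) stop("too few tumors outside the planted miRNA's subset")

    g_plant <- genes[1]
    module1 <- genes[2:31]     # co-regulated with the planted events
    g_b2 <- genes[32]; g_b3 <- genes[33]; g_b4 <- genes[34]
    module2 <- genes[35:64]    # co-regulated with the stage-4 distractor's CNA
    g_nocnv <- genes[65]
    background <- genes[66:n_genes]

    # planted deletions and the stage-4 distractor's deletions partition the
    # non-deregulated tumors, so neither DEG group sees the other's module
    half <- floor(length(rest) / 2)
    s_g <- rest[seq_len(half)]
    s_b4 <- rest[(half + 1):length(rest)]
    cna[g_plant, s_g] <- -0.5
    # expression: down in both event groups; extra drop in deleted samples so
    # the CNA-expression consistency pre-filter passes decisively
    mrna[g_plant, s_m] <- mrna[g_plant, s_m] - 2
    mrna[g_plant, s_g] <- mrna[g_plant, s_g] - 3
    for (g in module1) {
      mrna[g, s_m] <- mrna[g, s_m] - 2
      mrna[g, s_g] <- mrna[g, s_g] - 2
    }

    # distractor: deleted exactly where its miRNA is deregulated (co-occurring)
    m_b2 <- up_mirnas[2]
    s_b2 <- tumor_ids[cohort$truth[m_b2, ] == 1L]
    cna[g_b2, s_b2] <- -0.5
    mrna[g_b2, s_b2] <- mrna[g_b2, s_b2] - 2

    # distractor: exclusive deletions with concordant expression, but the
    # target is mildly induced (not repressed) in the miRNA-deregulated
    # patients — a non-functional interaction
    s_b3 <- sample(rest, min(20, length(rest)))
    cna[g_b3, s_b3] <- -0.5
    mrna[g_b3, s_b3] <- mrna[g_b3, s_b3] - 2
    mrna[g_b3, s_m] <- mrna[g_b3, s_m] + 0.8

    # distractor: passes stages 1-3 but its pathway footprint is disjoint
    cna[g_b4, s_b4] <- -0.5
    mrna[g_b4, s_m] <- mrna[g_b4, s_m] - 2
    mrna[g_b4, s_b4] <- mrna[g_b4, s_b4] - 3
    for (g in module2) mrna[g, s_b4] <- mrna[g, s_b4] - 2

    sets <- c(
      list(PW_PLANT1 = c(g_plant, module1[1:15]),
           PW_PLANT2 = module1[10:30],
           PW_ALT1 = c(g_b4, module2[1:15]),
           PW_ALT2 = module2[10:30]),
      setNames(lapply(seq_len(21), function(i)
        background[((i - 1) * 10 + 1):(i * 10)]),
        sprintf("PW_BG%02d", seq_len(21))))

    interactions <- data.frame(
      mirna_id = c(m_plant, m_plant, m_b2, m_plant, m_plant, m_plant),
      gene_id = c(g_plant, g_nocnv, g_b2, g_b3, g_b4, background[1]),
      source_count = c(3L, 2L, 2L, 2L, 2L, 1L),
      stringsAsFactors = FALSE)

    list(mrna = expression_matrix(mrna, "log2"),
         normal_samples = normal_ids,
         cna_log2 = cna,
         interactions = interactions,
         sets = gene_sets(sets),
         planted = list(mirna = m_plant, gene = g_plant,
                        mirna_samples = s_m, cna_samples = s_g,
                        pathways = c("PW_PLANT1", "PW_PLANT2")),
         distractors = data.frame(
           mirna_id = c(m_plant, m_b2, m_plant, m_plant, m_plant),
           gene_id = c(g_nocnv, g_b2, g_b3, g_b4, background[1]),
           fails = c("stage1", "stage1", "stage2", "stage4", "source_filter"),
           stringsAsFactors = FALSE))
  })
}
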
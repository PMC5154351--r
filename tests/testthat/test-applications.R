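test_that("subtype enrichment matches the hypergeometric tail cell for cell", {
  withr::local_seed(31)
  samples <- sprintf("p%03d", 1:100)
  calls <- matrix(0L, 2, 100, dimnames = list(c("mX", "mY"), samples))
  sub <- rep(c("LuminalA", "Basal-like"), c(20, 80))
  # all 10 up-calls of mX inside the 20-sample subtype
  calls["mX", 1:10] <- 1L
  calls["mY", sample(100, 30)] <- -1L
  ann <- data.frame(sample_id = samples, condition = "tumor", subtype = sub)
  res <- subtype_enrichment(structure(list(calls = calls), class = "reo_calls"), ann)
  row <- res[res$mirna == "mX" & res$subtype == "LuminalA" & res$direction == "up", ]
  expect_equal(row$p, hypergeom_tail(100, 20, 10, 10, "upper"), tolerance = 1e-12)
  expect_equal(row$p, sum(hyper_pmf_oracle(100, 20, 10)[11]), tolerance = 1e-12)
  expect_true(row$significant)

  # a subtype equal to the universe can never be enriched
  ann_all <- data.frame(sample_id = samples, condition = "tumor", subtype = "LuminalB")
  res_all <- subtype_enrichment(structure(list(calls = calls), class = "reo_calls"),
                                ann_all)
  expect_true(all(res_all$p == 1))

  # directions with no calls are skipped
  expect_false(any(res$mirna == "mX" & res$direction == "down"))
})

test_that("exclusivity test is the lower hypergeometric tail on the overlap", {
  uni <- sprintf("s%d", 1:40)
  a <- uni[1:20]; b <- uni[21:40]
  expect_equal(exclusivity_test(a, b, uni),
               hyper_pmf_oracle(40, 20, 20)[1], tolerance = 1e-12)
  expect_lt(exclusivity_test(a, b, uni), 1e-10)
  expect_equal(exclusivity_test(uni, b, uni), 1)
  expect_error(exclusivity_test(a, b, character(0)), "empty universe")

  # the published worked example's inputs give a small lower tail
  p_worked <- exclusivity_test(sprintf("d%d", 1:214),
                               c(sprintf("d%d", 1:35), sprintf("m%d", 1:119)),
                               c(sprintf("d%d", 1:214), sprintf("m%d", 1:119),
                                 sprintf("o%d", 1:410)))
  expect_equal(p_worked, hypergeom_tail(743, 214, 154, 35, "lower"), tolerance = 1e-12)
  expect_lt(p_worked, 0.05)
})

test_that("direction compatibility covers the coordinated loss/gain pairings", {
  expect_true(direction_compatible("up", "DEL"))
  expect_true(direction_compatible("down", "AMP"))
  expect_true(direction_compatible("up", "deleted"))
  expect_false(direction_compatible("up", "AMP"))
  expect_false(direction_compatible("down", "DEL"))
  expect_false(direction_compatible("up", "NEUT"))
})

test_that("target consistency demands the expected shift in both event groups", {
  withr::local_seed(33)
  samples <- c(sprintf("m%02d", 1:20), sprintf("c%02d", 1:20), sprintf("n%02d", 1:20))
  g <- rnorm(60, 8, 0.5)
  mk <- function(v) expression_matrix(matrix(v, 1, 60, dimnames = list("G", samples)))
  mirna_only <- samples[1:20]; cna_only <- samples[21:40]; normal <- samples[41:60]

  both <- g; both[1:40] <- both[1:40] - 2
  r <- target_consistency(mk(both), mirna_only, cna_only, normal, "G", "down")
  expect_true(r$pass)
  expect_lt(r$p_mirna, 0.05); expect_lt(r$p_cna, 0.05)

  one <- g; one[21:40] <- one[21:40] - 2     # shift only in the CNA group
  expect_false(target_consistency(mk(one), mirna_only, cna_only, normal,
                                  "G", "down")$pass)

  upb <- g; upb[1:40] <- upb[1:40] + 2       # wrong direction
  expect_false(target_consistency(mk(upb), mirna_only, cna_only, normal,
                                  "G", "down")$pass)

  small <- target_consistency(mk(g), samples[1], cna_only, normal, "G", "down")
  expect_false(small$pass)
  expect_match(small$reason, "2 samples")
  expect_error(target_consistency(mk(g), mirna_only, c(mirna_only[1], cna_only),
                                  normal, "G", "down"), "disjoint")
})

test_that("DEG detection recovers planted shifts and stays quiet on nulls", {
  withr::local_seed(34)
  genes <- sprintf("g%04d", 1:1000)
  samples <- c(sprintf("a%02d", 1:25), sprintf("b%02d", 1:25))
  m <- matrix(rnorm(1000 * 50, 8, 1), 1000, 50, dimnames = list(genes, samples))
  group <- samples[1:25]; normal <- samples[26:50]

  # null: split halves of one population
  expect_lte(length(deg_detect(expression_matrix(m), group, normal)), 2)

  planted <- genes[1:50]
  m2 <- m; m2[planted, group] <- m2[planted, group] + 3
  hits <- deg_detect(expression_matrix(m2), group, normal)
  expect_true(all(planted %in% hits))
  expect_length(deg_detect(expression_matrix(m2), group, normal, fdr = 0), 0)

  # false-discovery fraction stays near the nominal FDR on average
  fdp <- replicate(5, {
    mm <- matrix(rnorm(1000 * 50, 8, 1), 1000, 50, dimnames = list(genes, samples))
    mm[planted, group] <- mm[planted, group] + 3
    h <- deg_detect(expression_matrix(mm), group, normal)
    length(setdiff(h, planted)) / max(length(h), 1)
  })
  expect_lt(mean(fdp), 0.06)

  # one gene cross-checked against stats::t.test
  pvec <- reodiff:::row_welch_p(m2, group, normal)
  expect_equal(unname(pvec["g0007"]),
               stats::t.test(m2["g0007", group], m2["g0007", normal])$p.value,
               tolerance = 1e-12)
})

test_that("pathway enrichment ranks the matching pathway first and calibrates", {
  withr::local_seed(35)
  genes <- sprintf("g%03d", 1:200)
  sets <- gene_sets(c(list(target = genes[1:20]),
                      setNames(lapply(1:9, function(i) genes[(i * 20 + 1):(i * 20 + 20)]),
                               sprintf("bg%d", 1:9))))
  res <- pathway_enrichment(genes[1:20], sets, genes)
  expect_identical(res$pathway[1], "target")
  expect_equal(res$p[1], hypergeom_tail(200, 20, 20, 20, "upper"), tolerance = 1e-12)

  # random lists light up ~alpha of the catalogue
  hits <- replicate(50, nrow(pathway_enrichment(sample(genes, 20), sets, genes)))
  expect_lt(mean(hits) / 10, 0.12)

  expect_equal(nrow(pathway_enrichment(character(0), sets, genes)), 0)
  # disjoint gene list: every pathway at p = 1, nothing reported
  expect_equal(nrow(pathway_enrichment(genes[1:10], gene_sets(list(s = genes[51:60])),
                                       genes)), 0)
})

test_that("pathway overlap significance reproduces the published-count verdict", {
  catalogue <- sprintf("pw%03d", 1:234)
  a <- catalogue[1:13]; b <- c(catalogue[10:13], catalogue[100:117])
  expect_length(intersect(a, b), 4)
  p <- pathway_overlap_test(a, b, 234)
  expect_equal(p, hypergeom_tail(234, 13, 22, 4, "upper"), tolerance = 1e-12)
  expect_lt(p, 0.05)
  expect_equal(pathway_overlap_test(catalogue[1:5], catalogue[6:10], 234), 1)
  expect_equal(pathway_overlap_test(catalogue, catalogue, 234), 1)
})

test_that("the four-stage exclusivity screen recovers the planted pair only", {
  syn <- default_cohort()
  fit <- reo_fit(syn$normals, syn$tumors)
  calls <- predict(fit, syn$tumors)
  omics <- generate_linked_omics(syn)
  cna <- call_copy_number(omics$cna_log2)
  kept <- filter_cna_expression_consistent(cna, omics$mrna)
  cna <- cna[rownames(cna) %in% kept, , drop = FALSE]
  ix <- filter_interactions(omics$interactions)
  expect_false(any(ix$source_count < 2))
  res <- find_exclusive_pairs(calls, cna, ix, omics$mrna,
                              omics$normal_samples, omics$sets)

  hit <- res[res$verdict, ]
  expect_equal(nrow(hit), 1)
  expect_identical(hit$mirna_id, omics$planted$mirna)
  expect_identical(hit$gene_id, omics$planted$gene)
  expect_lt(hit$exclusivity_p, 0.05)
  expect_lt(hit$overlap_p, 0.05)

  # the pathway-disjoint distractor fails stage 4 alone
  d4 <- omics$distractors[omics$distractors$fails == "stage4", ]
  row <- res[res$mirna_id == d4$mirna_id & res$gene_id == d4$gene_id, ]
  expect_true(row$stage1 && row$stage2 && row$stage3)
  expect_false(row$stage4)
  expect_equal(row$pathway_overlap, 0)

  # stage bookkeeping: each stage admits no more pairs than the one before
  n_reached <- c(sum(!is.na(res$stage1)), sum(res$stage1, na.rm = TRUE),
                 sum(res$stage2, na.rm = TRUE), sum(res$stage3, na.rm = TRUE),
                 sum(res$stage4, na.rm = TRUE))
  expect_true(all(diff(n_reached) <= 0))

  # tightening any alpha never adds a verdict
  tight <- find_exclusive_pairs(calls, cna, ix, omics$mrna,
                                omics$normal_samples, omics$sets,
                                thresholds = list(exclusivity_alpha = 0.01,
                                                  overlap_alpha = 0.01))
  expect_true(all(paste(tight$mirna_id, tight$gene_id)[tight$verdict] %in%
                  paste(res$mirna_id, res$gene_id)[res$verdict]))

  empty <- find_exclusive_pairs(calls, cna, ix[0, ], omics$mrna,
                                omics$normal_samples, omics$sets)
  expect_equal(nrow(empty), 0)
})

test_that("survival grouping applies the direction filter and the log-rank test", {
  withr::local_seed(36)
  n <- 200
  samples <- sprintf("p%03d", 1:n)
  calls <- matrix(0L, 1, n, dimnames = list("mS", samples))
  dereg <- 1:80
  calls["mS", dereg] <- -1L
  calls["mS", 81:90] <- 1L     # up calls land in "others" under direction = down
  base_rate <- 1 / 500
  times <- c(rexp(80, base_rate * 2.5), rexp(120, base_rate))
  ann <- data.frame(sample_id = samples, condition = "tumor",
                    survival_time = times, event = 1L)
  sg <- survival_grouping(structure(list(calls = calls), class = "reo_calls"),
                          ann, "mS", direction = "down")
  expect_equal(sg$n_deregulated, 80)
  expect_identical(unname(sg$labels[samples[85]]), "others")
  expect_lt(sg$logrank_p, 0.05)

  # identical survival between groups: p = 1
  ann2 <- ann; ann2$survival_time <- rep(c(5, 10), n / 2)
  lab <- rep(c(0L, 0L, 1L, 1L), n / 4)  # both groups see the same {5, 10} mix
  calls2 <- calls; calls2["mS", ] <- lab
  sg2 <- survival_grouping(structure(list(calls = calls2), class = "reo_calls"),
                           ann2, "mS")
  expect_equal(sg2$logrank_p, 1, tolerance = 1e-9)

  none <- calls; none["mS", ] <- 0L
  sg3 <- survival_grouping(structure(list(calls = none), class = "reo_calls"),
                           ann, "mS")
  expect_true(is.na(sg3$logrank_p))
  expect_match(sg3$reason, "empty")
})
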
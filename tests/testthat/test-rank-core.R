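test_that("within-sample ordering comparison is strict with explicit ties", {
  expect_identical(compare_ordering(1, 2), "less")
  expect_identical(compare_ordering(2, 1), "greater")
  expect_identical(compare_ordering(5, 5), "tie")
  expect_error(compare_ordering(Inf, 1), "finite")
})

test_that("stable pairs need support strictly above the threshold", {
  # A < B in all 5 samples
  m <- toy_matrix(rbind(A = 1:5, B = 6:10))
  sp <- find_stable_pairs(m)
  expect_equal(nrow(sp), 1)
  expect_identical(sp$low, "A")
  expect_equal(sp$support, 1)

  # A < B in exactly 19/20 samples: 0.95 is NOT > 0.95
  v <- rbind(A = rep(1, 20), B = rep(2, 20)); v["B", 20] <- 0
  m2 <- toy_matrix(v)
  expect_equal(nrow(find_stable_pairs(m2)), 0)
  expect_equal(nrow(find_stable_pairs(m2, threshold = 0.9)), 1)

  # 80/81 samples = 98.8% is stable, majority orientation reported
  v3 <- rbind(A = rep(2, 81), B = rep(1, 81)); v3["B", 81] <- 3
  sp3 <- find_stable_pairs(toy_matrix(v3))
  expect_identical(sp3$low, "B")
  expect_equal(sp3$support, 80 / 81)

  # ties count as violations of both orientations
  vt <- rbind(A = rep(1, 20), B = c(rep(2, 18), 1, 1))
  expect_equal(nrow(find_stable_pairs(toy_matrix(vt))), 0)   # support 18/20
  expect_error(find_stable_pairs(m, threshold = 1.01), "\\(0, 1\\)")
})

test_that("reversal Fisher test builds the keep/flip table with ties as flips", {
  normals <- toy_matrix(rbind(A = rep(1, 10), B = rep(2, 10)))
  cancers <- toy_matrix(rbind(A = c(rep(3, 6), 1, 1, 1, 1),
                              B = c(rep(2, 9), 1)),
                        samples = sprintf("t%02d", 1:10))
  sp <- list(low = "A", high = "B")
  r <- fisher_reversal_test(sp, normals, cancers)
  expect_equal(r$normal_keep, 10)
  expect_equal(r$cancer_keep, 3)       # strict A < B in 3 samples; tie -> flip
  expect_equal(r$cancer_flip, 7)
  expect_equal(r$p, fisher_oracle(10, 0, 3, 7), tolerance = 1e-12)

  # homogeneous proportions give p = 1
  same <- fisher_reversal_test(sp, normals, toy_matrix(
    rbind(A = rep(1, 10), B = rep(2, 10)), samples = sprintf("u%02d", 1:10)))
  expect_equal(same$p, 1)

  # the 98.8% vs 13.6% training example, counts 80/1 and 11/70
  r2p <- reodiff:::fisher2x2_p(80, 1, 70, 11)
  expect_equal(r2p, fisher_oracle(80, 1, 70, 11), tolerance = 1e-12)
  expect_equal(r2p, stats::fisher.test(rbind(c(80, 1), c(70, 11)))$p.value,
               tolerance = 1e-10)

  # fully reversed table against brute force
  expect_equal(reodiff:::fisher2x2_p(10, 0, 0, 10), fisher_oracle(10, 0, 0, 10),
               tolerance = 1e-14)
  expect_error(fisher_reversal_test(sp, normals, normals[, 0]), "empty")
})

test_that("reversal selection applies BH and the directionality clause", {
  cand <- data.frame(low = "A", high = "B", normal_keep = 20, normal_flip = 0,
                     cancer_keep = 5, cancer_flip = 15, p = 0.01)
  sel <- select_reversal_pairs(cand)
  expect_equal(sel$q, 0.01)
  expect_equal(nrow(sel), 1)

  # significant but flipping in the wrong cohort is rejected
  wrong <- data.frame(low = "A", high = "B", normal_keep = 5, normal_flip = 15,
                      cancer_keep = 20, cancer_flip = 0, p = 1e-6)
  expect_equal(nrow(select_reversal_pairs(wrong)), 0)

  # uniform null p-values yield essentially no survivors at FDR 0.1
  withr::local_seed(5)
  null <- data.frame(low = sprintf("a%d", 1:100), high = sprintf("b%d", 1:100),
                     normal_keep = 19, normal_flip = 1,
                     cancer_keep = 10, cancer_flip = 10, p = runif(100))
  expect_lte(nrow(select_reversal_pairs(null)), 2)

  # lowering the FDR never adds pairs
  withr::local_seed(6)
  mix <- data.frame(low = sprintf("a%d", 1:50), high = sprintf("b%d", 1:50),
                    normal_keep = 20, normal_flip = 0,
                    cancer_keep = 10, cancer_flip = 10,
                    p = c(runif(25, 0, 1e-3), runif(25)))
  kept <- lapply(c(0.2, 0.1, 0.05, 0.01), function(f)
    rownames(select_reversal_pairs(mix, fdr = f)))
  for (i in seq_len(length(kept) - 1))
    expect_true(all(kept[[i + 1]] %in% kept[[i]]))
})

test_that("group-level directions need a significant shift", {
  withr::local_seed(8)
  normals <- toy_matrix(matrix(rnorm(3 * 30, mean = c(5, 9, 7), sd = 0.5), 3, 30),
                        features = c("up1", "down1", "flat1"))
  cancers <- toy_matrix(matrix(rnorm(3 * 30, mean = c(8, 2, 7), sd = 0.5), 3, 30),
                        features = c("up1", "down1", "flat1"),
                        samples = sprintf("t%02d", 1:30))
  d <- compute_directions(cancers, normals)
  dir <- setNames(d$direction, d$mirna)
  expect_identical(dir[["up1"]], "up")
  expect_identical(dir[["down1"]], "down")
  expect_identical(dir[["flat1"]], "none")

  # identical cohorts are all none
  expect_true(all(compute_directions(normals, normals)$direction == "none"))

  # the raw-sign rule is available
  raw <- compute_directions(cancers, normals, alpha = NULL)
  expect_true(all(raw$direction[raw$effect != 0] != "none"))
  expect_error(compute_directions(cancers[1:2, ], normals), "share")
})

test_that("implied direction attributes the reversal to the moved member", {
  rp <- list(low = "A", high = "B")
  expect_identical(implied_direction(rp, "A"), "up")
  expect_identical(implied_direction(rp, "B"), "down")
  expect_error(implied_direction(rp, "C"), "not a member")
  for (pair in list(list(low = "x", high = "y"), list(low = "m1", high = "m2")))
    expect_false(implied_direction(pair, pair$low) == implied_direction(pair, pair$high))
})

test_that("panels keep the k least-variable direction-consistent partners", {
  withr::local_seed(77)
  dirs <- data.frame(mirna = c("T", paste0("P", 1:5), "Q"),
                     effect = c(2, rep(0.1, 5), -2), p = 0,
                     direction = c("up", rep("up", 5), "down"))
  rev <- data.frame(low = "T", high = paste0("P", 1:5), p = 1e-4, q = 1e-3)
  train <- toy_matrix(rbind(
    T = rnorm(20, 5, 0.1),
    P1 = rnorm(20, 8, 0.01), P2 = rnorm(20, 8, 0.2), P3 = rnorm(20, 8, 0.05),
    P4 = rnorm(20, 8, 0.8), P5 = rnorm(20, 8, 0.02), Q = rnorm(20, 9, 0.1)),
    scale = "log2")
  pan <- build_panels(rev, dirs, train, k = 3)
  expect_equal(nrow(pan), 3)
  expect_setequal(pan$partner, c("P1", "P5", "P3"))
  expect_true(all(diff(pan$partner_cv) >= 0))

  # fewer than k pairs: all retained
  pan2 <- build_panels(rev[1:2, ], dirs, train, k = 3)
  expect_equal(nrow(pan2), 2)

  # ties in CV break lexicographically by partner id
  train2 <- train
  for (p in c("P2", "P3", "P4", "P5")) train2[p, ] <- train2["P1", ]
  pan3 <- build_panels(rev, dirs, train2, k = 2)
  expect_identical(pan3$partner, c("P1", "P2"))

  # a pair whose implied direction mismatches the target's is dropped
  dirs_down <- dirs; dirs_down$direction[1] <- "down"
  expect_equal(nrow(build_panels(rev, dirs_down, train, k = 3)), 0)
  expect_error(build_panels(rev, dirs, train, k = 0), "k must be")
})

test_that("individual calls need a strict majority of tumor-state orderings", {
  panel <- data.frame(target = "T", direction = "up",
                      partner = c("P1", "P2", "P3"), partner_cv = 0.1)
  s <- c(T = 5, P1 = 4, P2 = 4.5, P3 = 6)      # holds for 2 of 3
  expect_equal(call_sample(s, panel), list(call = "up", votes = 2L))
  s2 <- c(T = 5, P1 = 4, P2 = 6, P3 = 6)       # 1 of 3
  expect_equal(call_sample(s2, panel)$call, "none")
  s3 <- c(T = 5, P1 = 5, P2 = 4, P3 = 6)       # tie never votes
  expect_equal(call_sample(s3, panel)$votes, 1L)

  # small panels: 1 of 2 is not a majority; 1 of 1 is
  expect_equal(call_sample(s2, panel[1:2, ])$call, "none")
  expect_equal(call_sample(s, panel[1, , drop = FALSE]),
               list(call = "up", votes = 1L))
  expect_error(call_sample(c(T = 5), panel), "lacks values")

  down <- data.frame(target = "D", direction = "down", partner = c("P1", "P2"),
                     partner_cv = 0.1)
  expect_equal(call_sample(c(D = 1, P1 = 2, P2 = 3), down)$call, "down")
})

test_that("cohort calling matches per-sample calls and is sample-equivariant", {
  panels <- data.frame(target = c("T", "T", "D"), direction = c("up", "up", "down"),
                       partner = c("P1", "P2", "P1"), partner_cv = 0.1)
  cohort <- toy_matrix(rbind(T = c(5, 1), D = c(0.5, 9), P1 = c(2, 4), P2 = c(3, 5)),
                       samples = c("sA", "sB"))
  cc <- call_cohort(cohort, panels)
  expect_identical(dim(cc$calls), c(2L, 2L))
  for (s in colnames(cohort)) {
    one <- call_sample(cohort[, s], panels[panels$target == "T", ])
    expect_equal(unname(cc$votes["T", s]), one$votes)
    expect_equal(unname(cc$calls["T", s]),
                 switch(one$call, up = 1L, down = -1L, none = 0L))
  }
  perm <- call_cohort(cohort[, c("sB", "sA")], panels)
  expect_identical(perm$calls, cc$calls[, c("sB", "sA")])
  expect_error(call_cohort(cohort[1:2, ], panels), "lacks panel miRNAs")
  empty <- call_cohort(cohort, panels[0, ])
  expect_identical(nrow(empty$calls), 0L)
})
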
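test_that("compute_metrics implements the six criteria and their edge cases", {
  # perfect classifier
  m <- compute_metrics(TP = 50, FP = 0, TN = 70, FN = 0)
  expect_equal(unlist(m[c("Sn", "Sp", "Acc", "PPV", "MCC", "Gmean")]),
               c(Sn = 1, Sp = 1, Acc = 1, PPV = 1, MCC = 1, Gmean = 1))
  # all-positive caller on balanced data
  m <- compute_metrics(TP = 50, FP = 50, TN = 0, FN = 0)
  expect_equal(m$Sn, 1); expect_equal(m$Sp, 0)
  expect_equal(m$Gmean, 0); expect_equal(m$MCC, 0)
  # no positive calls: PPV undefined, flagged
  m <- compute_metrics(TP = 0, FP = 0, TN = 50, FN = 50)
  expect_true(m$ppv_undefined); expect_true(is.nan(m$PPV))
  expect_error(compute_metrics(TP = 0, FP = 0, TN = 0, FN = 5), "N")
  expect_error(compute_metrics(TP = 5, FP = 0, TN = 0, FN = -1),
               "non-negative")
  # Gmean^2 recovers Sn * Sp exactly
  m <- compute_metrics(TP = 13, FP = 29, TN = 31, FN = 7)
  expect_equal(m$Gmean^2, m$Sn * m$Sp, tolerance = 1e-12)
})

test_that("gmean matches its closed form and validates inputs", {
  expect_equal(gmean(1, 1), 1)
  expect_equal(round(gmean(0.680, 0.728), 3), 0.704)
  expect_equal(round(gmean(0.665, 0.719), 3), 0.691)
  expect_error(gmean(1.2, 0.5), "0, 1")
})

test_that("oversample_to_balance duplicates cyclically to the exact target", {
  x <- seq_len(1959)
  o <- oversample_to_balance(x, 4535, seed = 1)
  expect_length(o, 4535)
  expect_equal(attr(o, "fold"), 4535 / 1959)
  expect_equal(round(attr(o, "fold"), 2), 2.31)
  # every original item appears floor(fold) or ceiling(fold) times
  tab <- table(o)
  expect_true(all(tab %in% c(2L, 3L)))
  expect_equal(round(4535 / 1959, 2), 2.31)
  expect_equal(round(15475 / 8059, 2), 1.92)
  expect_identical(oversample_to_balance(x, length(x)), x,
                   ignore_attr = TRUE)
  expect_error(oversample_to_balance(x, 10), "target_size")
  # remainder draw is seeded
  expect_identical(oversample_to_balance(x, 4535, seed = 7),
                   oversample_to_balance(x, 4535, seed = 7))
})

test_that("cross_validate separates separable data and is seed-deterministic", {
  pos <- motif_contexts(60, L = 21, p = 0.05, seed = 31)
  neg <- rand_context(90, 21, seed = 32)
  dp <- dist_params(w = 0.5, L1 = 21L, L2 = 11L)
  # gamma = 0.1 over distances <= 1 keeps the kernel nearly flat, so a
  # hard-margin-like fit of this tiny separable sample needs a larger cost
  cv <- cross_validate(pos, neg, nfolds = 5, dp = dp, seed = 2, C = 10)
  expect_gt(cv$pooled$Acc, 0.95)
  # pooled counts cover every instance exactly once
  expect_identical(cv$pooled$P + cv$pooled$N, length(pos) + length(neg))
  expect_identical(nrow(cv$per_fold), 5L)
  cv2 <- cross_validate(pos, neg, nfolds = 5, dp = dp, seed = 2, C = 10)
  expect_identical(cv$decisions, cv2$decisions)
  expect_error(cross_validate(pos[1:3], neg, nfolds = 5, dp = dp),
               "nfolds")
})

test_that("label permutation drives pooled MCC to zero", {
  set.seed(33)
  all <- rand_context(120, 21)
  # both "classes" drawn from the same distribution = permuted labels
  cv <- cross_validate(all[1:60], all[61:120], nfolds = 5,
                       dp = dist_params(w = 0.5, L1 = 21L, L2 = 11L),
                       seed = 3)
  expect_lt(abs(cv$pooled$MCC), 0.1)
})

test_that("roc_auc matches the Mann-Whitney concordance oracle", {
  # decision value identical to the label: perfect ranking
  expect_equal(roc_auc(c(1, 1, -1, -1), c(1, 1, -1, -1))$auc, 1)
  set.seed(34)
  for (i in 1:25) {
    n <- sample(6:25, 1)
    y <- c(rep(1L, 3), sample(c(1L, -1L), n - 3, replace = TRUE),
           rep(-1L, 3))
    dv <- round(rnorm(length(y)), 1)  # coarse values force ties
    pos <- dv[y == 1L]; neg <- dv[y == -1L]
    pairs <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
    expect_equal(roc_auc(dv, y)$auc, mean(pairs))
  }
  # independent scores: AUC near 1/2
  set.seed(35)
  y <- sample(c(1L, -1L), 2000, replace = TRUE)
  dv <- rnorm(2000)
  expect_lt(abs(roc_auc(dv, y)$auc - 0.5), 0.05)
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")
})

test_that("AUC is invariant under strictly monotone transforms", {
  set.seed(36)
  y <- sample(c(1L, -1L), 200, replace = TRUE)
  dv <- rnorm(200)
  a <- roc_auc(dv, y)$auc
  expect_equal(roc_auc(exp(dv), y)$auc, a)
  expect_equal(roc_auc(atan(dv) * 3 + 7, y)$auc, a)
})

test_that("sweep_w endpoints equal pure-distance runs and rows follow the grid", {
  pos <- motif_contexts(40, L = 21, p = 0.1, seed = 41)
  neg <- rand_context(50, 21, seed = 42)
  dp <- dist_params(w = 0.9, L1 = 21L, L2 = 11L)  # w here is ignored
  tab <- sweep_w(pos, neg, w_grid = c(0, 0.5, 1, 0.5), dp_base = dp,
                 nfolds = 3, seed = 5)
  expect_identical(nrow(tab), 4L)
  expect_identical(tab$w, c(0, 0.5, 1, 0.5))
  # duplicated grid points give identical metrics
  expect_equal(tab[2, -1], tab[4, -1], ignore_attr = TRUE)
  cv0 <- cross_validate(pos, neg, nfolds = 3,
                        dp = dist_params(w = 0, L1 = 21L, L2 = 11L),
                        seed = 5)
  expect_equal(tab$Acc[1], cv0$pooled$Acc)
  expect_equal(tab$MCC[1], cv0$pooled$MCC)
  cv1 <- cross_validate(pos, neg, nfolds = 3,
                        dp = dist_params(w = 1, L1 = 21L, L2 = 11L),
                        seed = 5)
  expect_equal(tab$Acc[3], cv1$pooled$Acc)
})

test_that("sweep_length re-extracts per length and emits one row per case", {
  bench <- make_benchmark(genome_length = 30000L, n_sites = 25L,
                          motif = motif_model(21L,
                                              per_position_mutation_prob = 0.1),
                          rate = 5e-3, seed = 6)
  tab <- sweep_length(bench$genome,
                      bench$pos[c("chrom", "pos", "strand")],
                      bench$neg[c("chrom", "pos", "strand")],
                      lengths = c(11L, 21L), nfolds = 3, seed = 6)
  expect_identical(nrow(tab), 4L)
  expect_setequal(tab$distance, c("edit", "hamming"))
  expect_true(all(tab$length %% 2L == 1L))
  expect_error(sweep_length(bench$genome, bench$pos, bench$neg,
                            lengths = 10L), "odd")
})
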
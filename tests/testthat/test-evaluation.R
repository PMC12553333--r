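test_that("confusion counts and precision/recall match enumeration", {
  expect_identical(confusion_counts(c(1, 1, 0, 0), c(1, 0, 1, 0)),
                   c(TP = 1L, FP = 1L, TN = 1L, FN = 1L))
  y <- c(1, 1, 1, 0, 0)
  expect_identical(confusion_counts(y, y), c(TP = 3L, FP = 0L, TN = 2L, FN = 0L))
  set.seed(1)
  for (i in 1:20) {
    y <- sample(0:1, 50, replace = TRUE)
    p <- sample(0:1, 50, replace = TRUE)
    expect_identical(confusion_counts(y, p), oracle_confusion(y, p))
  }
  expect_error(confusion_counts(c(1, 0), c(1)), class = "pb_length_mismatch")
  pr <- precision_recall(c(TP = 1, FP = 1, TN = 1, FN = 1))
  expect_equal(unname(pr), c(0.5, 0.5), ignore_attr = TRUE)
  pr0 <- precision_recall(c(TP = 0, FP = 0, TN = 2, FN = 2))
  expect_identical(unname(pr0[["precision"]]), 0)
  expect_true(attr(pr0, "undefined_precision"))
})

test_that("ROC-AUC equals the Mann-Whitney pair statistic", {
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.3, 0.2)), 1.0)
  expect_equal(roc_auc(c(1, 0, 1, 0), c(0.9, 0.8, 0.3, 0.2)), 0.75)
  # rank invariance under monotone transforms
  y <- c(1, 0, 1, 0, 1, 0)
  s <- c(0.7, 0.2, 0.9, 0.5, 0.4, 0.1)
  expect_equal(roc_auc(y, s), roc_auc(y, exp(10 * s)))
  expect_error(roc_auc(c(1, 1), c(0.5, 0.2)), class = "pb_single_class")
})

test_that("PR-AUC equals average precision by threshold enumeration", {
  expect_equal(pr_auc(c(1, 0), c(0.9, 0.1)), 1.0)
  expect_equal(pr_auc(c(1, 0, 1), c(0.9, 0.8, 0.7)), 5 / 6)
  expect_error(pr_auc(c(0, 0), c(0.4, 0.2)), class = "pb_no_positives")
})

test_that("AUC kernels match brute-force oracles on tied random instances", {
  set.seed(99)
  for (i in 1:200) {
    n <- sample(4:50, 1)
    y <- sample(0:1, n, replace = TRUE)
    if (all(y == y[1L])) y[1L] <- 1 - y[1L]
    # coarse score grid forces plenty of ties
    s <- sample(seq(0, 1, by = 0.125), n, replace = TRUE)
    expect_equal(roc_auc(y, s), oracle_roc_auc(y, s), tolerance = 1e-12)
    expect_equal(pr_auc(y, s), oracle_pr_auc(y, s), tolerance = 1e-12)
  }
})

test_that("roc_auc(y, s) + roc_auc(y, -s) = 1 for tie-free scores", {
  set.seed(3)
  for (i in 1:20) {
    n <- sample(6:40, 1)
    y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    s <- sample(seq_len(1000), n) / 1000
    expect_equal(roc_auc(y, s) + roc_auc(y, -s), 1, tolerance = 1e-12)
  }
})

test_that("regression metrics follow their defining formulas", {
  y <- c(1, 2, 3, 4)
  expect_equal(unname(regression_metrics(y, y)), c(0, 0, 1, 1))
  expect_equal(regression_metrics(y, rep(mean(y), 4))[["r2"]], 0)
  expect_equal(regression_metrics(c(1, 2, 3), c(3, 2, 1))[["spearman"]], -1)
  expect_error(regression_metrics(c(2, 2, 2), c(1, 2, 3)),
               class = "pb_zero_variance")
  # Spearman is invariant under strictly monotone transforms
  set.seed(4)
  for (i in 1:10) {
    a <- rnorm(30); b <- rnorm(30)
    r0 <- regression_metrics(a, b)[["spearman"]]
    expect_equal(regression_metrics(a, exp(b))[["spearman"]], r0)
    expect_equal(regression_metrics(2 * a + 5, b)[["spearman"]], r0)
    # cross-check against the stats implementation
    expect_equal(r0, cor(a, b, method = "spearman"))
  }
})

test_that("macro F1 averages per-class F1 with empty classes scoring zero", {
  expect_equal(macro_f1(c(0, 1, 2), c(0, 1, 2), 3), 1.0)
  expect_equal(macro_f1(c(1, 1, 0, 0), c(1, 0, 1, 0), 2), 0.5)
  set.seed(12)
  for (i in 1:20) {
    y <- sample(0:9, 200, replace = TRUE)
    p <- sample(0:9, 200, replace = TRUE)
    expect_equal(macro_f1(y, p, 10), oracle_macro_f1(y, p, 10),
                 tolerance = 1e-12)
  }
  # accuracy reproduces the fraction-correct definition
  for (i in 1:10) {
    y <- sample(0:1, 40, replace = TRUE)
    p <- sample(0:1, 40, replace = TRUE)
    cc <- confusion_counts(y, p)
    expect_equal(accuracy(y, p), (cc[["TP"]] + cc[["TN"]]) / 40)
  }
})

test_that("metric reports are task-conditioned", {
  reg <- task_spec("r", "single", "sequence", "regression")
  pr <- data.frame(id = letters[1:5], pred = c(1, 2, 3, 4, 5))
  rep1 <- compute_metrics(reg, pr, c(1.1, 2.2, 2.9, 4.4, 4.8))
  expect_named(rep1, c("mse", "mae", "spearman", "r2"))
  bin <- task_spec("b", "single", "sequence", "binary")
  pb2 <- data.frame(id = letters[1:6], pred_class = c(1, 0, 1, 0, 1, 0),
                    prob.1 = c(0.1, 0.8, 0.2, 0.7, 0.3, 0.6),
                    prob.2 = c(0.9, 0.2, 0.8, 0.3, 0.7, 0.4))
  rep2 <- compute_metrics(bin, pb2, c(1, 0, 1, 0, 0, 1))
  expect_named(rep2, c("roc_auc", "pr_auc", "accuracy", "macro_f1"))
  expect_true(all(unlist(rep2) >= 0 & unlist(rep2) <= 1))
})

test_that("residue metrics pool non-pad residues across sequences", {
  rt <- task_spec("r", "single", "residue", "binary")
  truth <- list(c(0L, 1L, 0L), c(1L, 0L, 0L, 1L, 1L))
  preds <- data.frame(
    id = c(rep("a", 3), rep("b", 5)), position = c(1:3, 1:5),
    pred_class = c(0, 1, 0, 1, 0, 0, 1, 0),
    prob.1 = c(0.9, 0.2, 0.8, 0.1, 0.7, 0.6, 0.2, 0.55),
    prob.2 = c(0.1, 0.8, 0.2, 0.9, 0.3, 0.4, 0.8, 0.45))
  rep3 <- compute_metrics(rt, preds, truth)
  expect_identical(attr(rep3, "n"), 8L)  # 3 + 5 pooled residues
  expect_equal(rep3$accuracy, 7 / 8)
})

test_that("method comparison reproduces the Student t test", {
  a <- c(0.9, 0.91, 0.92); b <- c(0.5, 0.51, 0.52)
  cmp <- compare_methods(a, b, alpha = 0.01)
  ref <- t.test(a, b, var.equal = TRUE)
  expect_equal(cmp$t, unname(ref$statistic), tolerance = 1e-9)
  expect_equal(cmp$p_value, ref$p.value, tolerance = 1e-9)
  expect_identical(cmp$verdict, "significant")
  # Welch variant against its reference
  cw <- compare_methods(a, c(0.5, 0.6, 0.72, 0.8), welch = TRUE)
  rw <- t.test(a, c(0.5, 0.6, 0.72, 0.8))
  expect_equal(cw$p_value, rw$p.value, tolerance = 1e-9)
  set.seed(8)
  for (i in 1:20) {
    x <- rnorm(sample(3:6, 1)); y <- rnorm(sample(3:6, 1))
    expect_equal(compare_methods(x, y)$p_value,
                 t.test(x, y, var.equal = TRUE)$p.value, tolerance = 1e-6)
  }
})

test_that("identical replicates are never significant; few replicates error", {
  cmp <- compare_methods(c(0.7, 0.7, 0.7), c(0.7, 0.7, 0.7))
  expect_equal(cmp$p_value, 1)
  expect_identical(cmp$verdict, "not_significant")
  expect_error(compare_methods(0.5, 0.7), class = "pb_too_few_replicates")
})

test_that("leaderboards aggregate mean/sd and rank per metric", {
  res <- data.frame(model = rep(c("cnn", "gcn"), each = 3),
                    task = "t", seed = rep(1:3, 2),
                    roc_auc = c(0.9, 0.92, 0.91, 0.7, 0.72, 0.71),
                    mae = c(0.2, 0.21, 0.19, 0.1, 0.11, 0.09))
  lb <- leaderboard(res)
  expect_identical(nrow(lb), 2L)
  expect_equal(lb$roc_auc_mean[lb$model == "cnn"], 0.91)
  expect_identical(lb$roc_auc_rank[lb$model == "cnn"], 1L)
  expect_identical(lb$mae_rank[lb$model == "gcn"], 1L)  # lower is better
})
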
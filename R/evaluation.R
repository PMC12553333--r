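# Metric suite and multi-seed statistical comparison.
#
# Binary metrics derive from the four confusion counts; ROC-AUC is the
# Mann-Whitney pair statistic (ties count one half), PR-AUC is average
# precision (step-wise, not interpolated). Regression metrics are MSE, MAE,
# Spearman rank correlation (average ranks on ties), and the coefficient of
# determination. Residue tasks pool all non-pad residues across sequences
# before computing (micro pooling). Method comparison across replicate
# seeds uses a two-sided two-sample Student t test (equal variances by
# default; Welch by flag).

#' Confusion counts
#'
#' @param y_true,y_pred Equal-length binary (0/1) vectors.
#' @return Named integer vector `c(TP, FP, TN, FN)`.
#' @export
confusion_counts <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    pb_stop("pb_length_mismatch", "y_true and y_pred differ in length")
  }
  stopifnot(all(y_true %in% 0:1), all(y_pred %in% 0:1))
  c(TP = sum(y_true == 1 & y_pred == 1), FP = sum(y_true == 0 & y_pred == 1),
    TN = sum(y_true == 0 & y_pred == 0), FN = sum(y_true == 1 & y_pred == 0))
}

#' Precision and recall from confusion counts
#'
#' Zero-denominator convention: the value is 0 and the corresponding
#' `undefined_*` attribute flags it.
#'
#' @param counts Output of [confusion_counts()].
#' @return Named numeric `c(precision, recall)` with undefined flags as
#'   attributes.
#' @export
precision_recall <- function(counts) {
  pden <- counts[["TP"]] + counts[["FP"]]
  rden <- counts[["TP"]] + counts[["FN"]]
  out <- c(precision = if (pden > 0) counts[["TP"]] / pden else 0,
           recall = if (rden > 0) counts[["TP"]] / rden else 0)
  attr(out, "undefined_precision") <- pden == 0
  attr(out, "undefined_recall") <- rden == 0
  out
}

#' ROC-AUC
#'
#' Probability that a random positive outscores a random negative, ties
#' counting one half (the Mann-Whitney statistic); invariant under monotone
#' transforms of the scores.
#'
#' @param y_true Binary labels (both classes present).
#' @param scores Real-valued scores, higher = more positive.
#' @return Value in `[0, 1]`.
#' @export
roc_auc <- function(y_true, scores) {
  if (length(y_true) != length(scores)) {
    pb_stop("pb_length_mismatch", "labels and scores differ in length")
  }
  pos <- y_true == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) {
    pb_stop("pb_single_class", "ROC-AUC needs both classes present")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' PR-AUC (average precision)
#'
#' Step-wise average precision: the sum over positive-introducing
#' thresholds of precision times the recall increment. Tied scores enter as
#' one threshold group.
#'
#' @inheritParams roc_auc
#' @return Value in `[0, 1]`.
#' @export
pr_auc <- function(y_true, scores) {
  if (length(y_true) != length(scores)) {
    pb_stop("pb_length_mismatch", "labels and scores differ in length")
  }
  npos <- sum(y_true == 1)
  if (npos == 0L) pb_stop("pb_no_positives", "PR-AUC needs positive samples")
  o <- order(scores, decreasing = TRUE)
  ys <- y_true[o]; ss <- scores[o]
  grp <- cumsum(!duplicated(ss))            # threshold groups of tied scores
  tp_g <- tapply(ys, grp, sum)
  n_g <- tapply(ys, grp, length)
  tp <- cumsum(tp_g)
  n_at <- cumsum(n_g)
  prec <- tp / n_at
  drec <- diff(c(0, tp)) / npos
  sum(prec * drec)
}

#' Regression metrics
#'
#' Mean squared error, mean absolute error, Spearman rank correlation
#' (average ranks on ties), and the R-squared coefficient of determination.
#'
#' @param y_true,y_pred Equal-length numeric vectors, length >= 2.
#' @return Named numeric `c(mse, mae, spearman, r2)`.
#' @export
regression_metrics <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) >= 2L)
  mse <- mean((y_true - y_pred)^2)
  mae <- mean(abs(y_true - y_pred))
  sst <- sum((y_true - mean(y_true))^2)
  if (sst == 0) {
    pb_stop("pb_zero_variance",
            "Spearman and R2 are undefined for constant y_true")
  }
  rt <- rank(y_true, ties.method = "average")
  rp <- rank(y_pred, ties.method = "average")
  rho <- if (stats::sd(rp) == 0) 0 else stats::cor(rt, rp)
  c(mse = mse, mae = mae, spearman = rho,
    r2 = 1 - sum((y_true - y_pred)^2) / sst)
}

#' Macro-averaged F1
#'
#' Unweighted mean over classes of per-class F1; a class absent from both
#' truth and prediction contributes F1 = 0.
#'
#' @param y_true,y_pred Class labels in `[0, num_classes)`.
#' @param num_classes Number of classes.
#' @return Value in `[0, 1]`.
#' @export
macro_f1 <- function(y_true, y_pred, num_classes) {
  f1 <- vapply(seq_len(num_classes) - 1L, function(c) {
    tp <- sum(y_true == c & y_pred == c)
    fp <- sum(y_true != c & y_pred == c)
    fn <- sum(y_true == c & y_pred != c)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1L))
  mean(f1)
}

#' Accuracy
#'
#' @param y_true,y_pred Equal-length label vectors.
#' @return Fraction of correctly predicted samples.
#' @export
accuracy <- function(y_true, y_pred) mean(y_true == y_pred)

#' Task-conditioned metric report
#'
#' Regression tasks report `mse`, `mae`, `spearman`, `r2`; binary tasks
#' report `roc_auc`, `pr_auc`, `accuracy`, `macro_f1`; multiclass tasks
#' report `accuracy`, `macro_f1`. Residue-level tasks pool every non-pad
#' residue across sequences first.
#'
#' @param task A [task_spec()].
#' @param predictions Prediction table from [predict_records()].
#' @param truth Label vector (list of per-residue vectors for residue tasks).
#' @return A `pb_metric_report`: named list of metric values with the
#'   sample count as attribute `n`.
#' @export
compute_metrics <- function(task, predictions, truth) {
  if (task$level == "residue") {
    truth <- unlist(truth, use.names = FALSE)
    stopifnot(length(truth) == nrow(predictions))
  }
  out <- if (task$objective == "regression") {
    as.list(regression_metrics(truth, predictions$pred))
  } else if (task$objective == "binary") {
    score <- if ("prob.2" %in% names(predictions)) predictions$prob.2
             else predictions$prob    # P(class 1)
    pred_cls <- predictions$pred_class
    list(roc_auc = roc_auc(truth, score), pr_auc = pr_auc(truth, score),
         accuracy = accuracy(truth, pred_cls),
         macro_f1 = macro_f1(truth, pred_cls, 2L))
  } else {
    list(accuracy = accuracy(truth, predictions$pred_class),
         macro_f1 = macro_f1(truth, predictions$pred_class, task$num_classes))
  }
  structure(out, n = length(truth), class = "pb_metric_report")
}

#' Compare two methods over replicate seeds
#'
#' Two-sided two-sample t test on per-seed metric values; Student's
#' equal-variance statistic by default, Welch by flag. The verdict is
#' `"significant"` iff p < alpha.
#'
#' @param values_a,values_b Numeric vectors of per-seed values (>= 2 each).
#' @param alpha Significance level (default 0.05).
#' @param welch Use the Welch unequal-variance statistic.
#' @return A `pb_comparison`: t statistic, degrees of freedom, p value,
#'   alpha, verdict.
#' @export
compare_methods <- function(values_a, values_b, alpha = 0.05, welch = FALSE) {
  na <- length(values_a); nb <- length(values_b)
  if (na < 2L || nb < 2L) {
    pb_stop("pb_too_few_replicates",
            "need at least two replicate values per method")
  }
  ma <- mean(values_a); mb <- mean(values_b)
  va <- stats::var(values_a); vb <- stats::var(values_b)
  if (welch) {
    se2 <- va / na + vb / nb
    t_stat <- (ma - mb) / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  } else {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    t_stat <- (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  }
  p <- if (!is.finite(t_stat)) {
    if (isTRUE(all.equal(ma, mb))) 1 else 0
  } else {
    2 * stats::pt(-abs(t_stat), df)
  }
  structure(list(t = t_stat, df = df, p_value = p, alpha = alpha,
                 mean_a = ma, mean_b = mb,
                 verdict = if (p < alpha) "significant" else "not_significant"),
            class = "pb_comparison")
}

#' @export
print.pb_comparison <- function(x, ...) {
  cat(sprintf("t = %.4f (df %.2f), p = %.4g -> %s at alpha %.2g\n",
              x$t, x$df, x$p_value, x$verdict, x$alpha))
  invisible(x)
}

#' Aggregate per-seed metric reports into a leaderboard table
#'
#' One row per (model, task) with `mean +/- sd` per metric and an explicit
#' rank column per metric (rank 1 = best, direction-aware).
#'
#' @param results data.frame with columns `model`, `task`, `seed`, one
#'   column per metric.
#' @return A leaderboard data.frame.
#' @export
leaderboard <- function(results) {
  metric_cols <- setdiff(names(results), c("model", "task", "seed"))
  lower_better <- c("mse", "mae")
  rows <- list()
  for (tk in unique(results$task)) {
    sub <- results[results$task == tk, , drop = FALSE]
    agg <- lapply(split(sub, sub$model), function(g) {
      r <- list(model = g$model[1L], task = tk, n_seeds = nrow(g))
      for (m in metric_cols) {
        r[[paste0(m, "_mean")]] <- mean(g[[m]])
        r[[paste0(m, "_sd")]] <- stats::sd(g[[m]])
      }
      as.data.frame(r)
    })
    tab <- do.call(rbind, agg)
    for (m in metric_cols) {
      mu <- tab[[paste0(m, "_mean")]]
      tab[[paste0(m, "_rank")]] <-
        rank(if (m %in% lower_better) mu else -mu, ties.method = "min")
    }
    rows[[tk]] <- tab
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
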
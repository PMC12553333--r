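# Brute-force oracles, independent of the package's metric kernels.

oracle_confusion <- function(y, p) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(y)) {
    if (y[i] == 1 && p[i] == 1) tp <- tp + 1L
    if (y[i] == 0 && p[i] == 1) fp <- fp + 1L
    if (y[i] == 0 && p[i] == 0) tn <- tn + 1L
    if (y[i] == 1 && p[i] == 0) fn <- fn + 1L
  }
  c(TP = tp, FP = fp, TN = tn, FN = fn)
}

# ROC-AUC by exhaustive positive/negative pair enumeration
oracle_roc_auc <- function(y, s) {
  pos <- which(y == 1); neg <- which(y == 0)
  tot <- 0
  for (i in pos) for (j in neg) {
    tot <- tot + if (s[i] > s[j]) 1 else if (s[i] == s[j]) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# average precision by explicit threshold enumeration over tied-score groups
oracle_pr_auc <- function(y, s) {
  npos <- sum(y == 1)
  thr <- sort(unique(s), decreasing = TRUE)
  ap <- 0; prev_rec <- 0
  for (t in thr) {
    sel <- s >= t
    prec <- sum(y[sel] == 1) / sum(sel)
    rec <- sum(y[sel] == 1) / npos
    ap <- ap + prec * (rec - prev_rec)
    prev_rec <- rec
  }
  ap
}

oracle_macro_f1 <- function(y, p, C) {
  f <- numeric(C)
  for (c in 0:(C - 1L)) {
    tp <- sum(y == c & p == c); fp <- sum(y != c & p == c)
    fn <- sum(y == c & p != c)
    f[c + 1L] <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }
  mean(f)
}

# apply a node permutation to a peptide graph (for invariance tests)
permute_graph <- function(g, perm) {
  inv <- integer(length(perm))
  inv[perm] <- seq_along(perm)
  g$elements <- g$elements[perm]
  g$atom_names <- g$atom_names[perm]
  g$residue_of <- g$residue_of[perm]
  g$bonds$from <- inv[g$bonds$from]
  g$bonds$to <- inv[g$bonds$to]
  g
}

tiny_records <- function(n, task, seed = 1, len = c(12L, 20L), ...) {
  generate_records(generator_spec(task, n, length_range = len, seed = seed, ...))
}

pbns <- asNamespace("protbench")
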
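# Reverse-mode automatic differentiation on matrix values.
#
# A tape records every operation in creation order; ad_backward() walks it in
# reverse, so topological order is free. Values are plain numeric matrices;
# nodes are environments so gradient accumulation mutates in place. Operations
# accept either ad_node arguments or plain numerics (treated as constants).

ad_tape <- function() {
  e <- new.env(parent = emptyenv())
  e$nodes <- vector("list", 256L)
  e$n <- 0L
  class(e) <- "ad_tape"
  e
}

ad_node <- function(tape, value, parents = list(), backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$backward <- backward
  class(nd) <- "ad_node"
  if (!is.null(tape)) {
    n <- tape$n + 1L
    if (n > length(tape$nodes)) {
      tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
    }
    tape$nodes[[n]] <- nd
    tape$n <- n
  }
  nd
}

is_ad <- function(x) inherits(x, "ad_node")

ad_value <- function(x) if (is_ad(x)) x$value else x

# Wrap a plain array as a leaf (gradient is accumulated but nothing flows on).
ad_leaf <- function(tape, value) ad_node(tape, value)

ad_accumulate <- function(node, g) {
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(node)
}

#' @keywords internal
ad_backward <- function(tape, loss) {
  stopifnot(is_ad(loss), length(loss$value) == 1L)
  loss$grad <- 1
  for (i in seq.int(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$grad) || is.null(nd$backward)) next
    pg <- nd$backward(nd$grad)
    ps <- nd$parents
    for (j in seq_along(ps)) {
      p <- ps[[j]]
      if (is_ad(p) && !is.null(pg[[j]])) ad_accumulate(p, pg[[j]])
    }
  }
  invisible(loss)
}

## ---- elementwise and linear algebra ----

ad_matmul <- function(tape, a, b) {
  av <- ad_value(a); bv <- ad_value(b)
  ad_node(tape, av %*% bv, parents = list(a, b), backward = function(g) {
    list(g %*% t(bv), crossprod(av, g))
  })
}

# x %*% W + b with b broadcast over rows; b may be NULL
ad_linear <- function(tape, x, W, b = NULL) {
  xv <- ad_value(x); Wv <- ad_value(W)
  out <- xv %*% Wv
  if (!is.null(b)) out <- sweep(out, 2L, ad_value(b), "+")
  ad_node(tape, out, parents = list(x, W, b), backward = function(g) {
    list(g %*% t(Wv), crossprod(xv, g), if (is.null(b)) NULL else colSums(g))
  })
}

ad_add <- function(tape, a, b) {
  av <- ad_value(a); bv <- ad_value(b)
  ad_node(tape, av + bv, parents = list(a, b),
          backward = function(g) list(g, g))
}

ad_sub <- function(tape, a, b) {
  av <- ad_value(a); bv <- ad_value(b)
  ad_node(tape, av - bv, parents = list(a, b),
          backward = function(g) list(g, -g))
}

ad_hadamard <- function(tape, a, b) {
  av <- ad_value(a); bv <- ad_value(b)
  ad_node(tape, av * bv, parents = list(a, b),
          backward = function(g) list(g * bv, g * av))
}

ad_scale <- function(tape, x, s) {
  xv <- ad_value(x)
  ad_node(tape, xv * s, parents = list(x), backward = function(g) list(g * s))
}

# multiply each row i of x by scalar s[i] (s constant)
ad_row_scale <- function(tape, x, s) {
  xv <- ad_value(x)
  ad_node(tape, xv * s, parents = list(x), backward = function(g) list(g * s))
}

ad_concat_cols <- function(tape, a, b) {
  av <- ad_value(a); bv <- ad_value(b)
  na <- ncol(av)
  ad_node(tape, cbind(av, bv), parents = list(a, b), backward = function(g) {
    list(g[, seq_len(na), drop = FALSE], g[, -seq_len(na), drop = FALSE])
  })
}

## ---- nonlinearities ----

ad_relu <- function(tape, x) {
  xv <- ad_value(x)
  keep <- xv > 0
  ad_node(tape, xv * keep, parents = list(x),
          backward = function(g) list(g * keep))
}

ad_leaky_relu <- function(tape, x, alpha = 0.01) {
  xv <- ad_value(x)
  slope <- ifelse(xv > 0, 1, alpha)
  ad_node(tape, xv * slope, parents = list(x),
          backward = function(g) list(g * slope))
}

ad_sigmoid <- function(tape, x) {
  y <- stats::plogis(ad_value(x))
  ad_node(tape, y, parents = list(x),
          backward = function(g) list(g * y * (1 - y)))
}

ad_tanh <- function(tape, x) {
  y <- tanh(ad_value(x))
  ad_node(tape, y, parents = list(x),
          backward = function(g) list(g * (1 - y * y)))
}

# Row-wise softmax; `shift` (constant, e.g. -Inf attention mask) is added first.
ad_softmax_rows <- function(tape, x, shift = NULL) {
  xv <- ad_value(x)
  if (!is.null(shift)) xv <- xv + shift
  ex <- exp(xv - row_max(xv))
  y <- ex / rowSums(ex)
  ad_node(tape, y, parents = list(x), backward = function(g) {
    list((g - rowSums(g * y)) * y)
  })
}

# Inverted dropout; draws from the current RNG stream so training is seeded.
ad_dropout <- function(tape, x, p, training) {
  if (!training || p <= 0) return(x)
  xv <- ad_value(x)
  keep <- matrix(stats::runif(length(xv)) >= p, nrow(xv), ncol(xv)) / (1 - p)
  ad_node(tape, xv * keep, parents = list(x),
          backward = function(g) list(g * keep))
}

## ---- gather / scatter ----

# rows of x at idx (1-based); backward scatter-adds (plain assignment when
# the gather is injective — the common case for pooling and time slicing).
ad_rows <- function(tape, x, idx) {
  xv <- ad_value(x)
  nr <- nrow(xv)
  unique_idx <- anyDuplicated(idx) == 0L
  ad_node(tape, xv[idx, , drop = FALSE], parents = list(x), backward = function(g) {
    gx <- matrix(0, nr, ncol(g))
    if (unique_idx) {
      gx[idx, ] <- g
    } else {
      rs <- rowsum(g, group = idx, reorder = TRUE)
      gx[as.integer(rownames(rs)), ] <- rs
    }
    list(gx)
  })
}

# sum rows of x within groups 1..ngroups (group: integer vector per row)
ad_segment_sum <- function(tape, x, group, ngroups) {
  xv <- ad_value(x)
  rs <- rowsum(xv, group = group, reorder = TRUE)
  out <- matrix(0, ngroups, ncol(xv))
  out[as.integer(rownames(rs)), ] <- rs
  ad_node(tape, out, parents = list(x),
          backward = function(g) list(g[group, , drop = FALSE]))
}

# column-wise max within groups; groups with no rows are -Inf (disallowed here)
ad_segment_max <- function(tape, x, group, ngroups) {
  xv <- ad_value(x)
  nc <- ncol(xv)
  rows_by_g <- split(seq_len(nrow(xv)), group)
  out <- matrix(-Inf, ngroups, nc)
  arg <- matrix(NA_integer_, ngroups, nc)
  for (gname in names(rows_by_g)) {
    gi <- as.integer(gname)
    rows <- rows_by_g[[gname]]
    sub <- xv[rows, , drop = FALSE]
    a <- max.col(t(sub), ties.method = "first")
    out[gi, ] <- sub[cbind(a, seq_len(nc))]
    arg[gi, ] <- rows[a]
  }
  ad_node(tape, out, parents = list(x), backward = function(g) {
    gx <- matrix(0, nrow(xv), nc)
    ok <- which(!is.na(arg))
    ij <- arrayInd(ok, dim(arg))
    gx[cbind(arg[ok], ij[, 2L])] <- gx[cbind(arg[ok], ij[, 2L])] + g[ok]
    list(gx)
  })
}

# im2col for 1-D convolution: idx is an (nrow x K) integer matrix of source
# rows, 0 meaning "outside the sequence" (contributes zeros). Output is the
# horizontal concatenation of the K gathered blocks.
ad_im2col <- function(tape, x, idx) {
  xv <- ad_value(x)
  nc <- ncol(xv)
  K <- ncol(idx)
  xa <- rbind(matrix(0, 1L, nc), xv)
  blocks <- vector("list", K)
  for (k in seq_len(K)) blocks[[k]] <- xa[idx[, k] + 1L, , drop = FALSE]
  # each idx column is injective over its valid entries (a within-sequence
  # shift), so the scatter is a plain indexed add
  valid_k <- lapply(seq_len(K), function(k) which(idx[, k] > 0L))
  ad_node(tape, do.call(cbind, blocks), parents = list(x), backward = function(g) {
    gx <- matrix(0, nrow(xv), nc)
    for (k in seq_len(K)) {
      v <- valid_k[[k]]
      if (length(v) == 0L) next
      at <- idx[v, k]
      gx[at, ] <- gx[at, ] + g[v, ((k - 1L) * nc + 1L):(k * nc), drop = FALSE]
    }
    list(gx)
  })
}

## ---- normalization ----

ad_layer_norm <- function(tape, x, gamma, beta, eps = 1e-5) {
  xv <- ad_value(x)
  gv <- ad_value(gamma); bv <- ad_value(beta)
  n <- ncol(xv)
  mu <- rowMeans(xv)
  xc <- xv - mu
  v <- rowMeans(xc * xc)
  istd <- 1 / sqrt(v + eps)
  xhat <- xc * istd
  out <- sweep(sweep(xhat, 2L, gv, "*"), 2L, bv, "+")
  ad_node(tape, out, parents = list(x, gamma, beta), backward = function(g) {
    gh <- sweep(g, 2L, gv, "*")
    dx <- istd * (gh - rowMeans(gh) - xhat * rowMeans(gh * xhat))
    list(dx, colSums(g * xhat), colSums(g))
  })
}

# Batch normalization over rows (feature columns). `state` is an environment
# holding running_mean / running_var, updated only in training mode.
ad_batch_norm <- function(tape, x, gamma, beta, state, training,
                          momentum = 0.1, eps = 1e-5) {
  xv <- ad_value(x)
  gv <- ad_value(gamma); bv <- ad_value(beta)
  if (training && nrow(xv) > 1L) {
    mu <- colMeans(xv)
    xc <- sweep(xv, 2L, mu)
    v <- colMeans(xc * xc)
    state$running_mean <- (1 - momentum) * state$running_mean + momentum * mu
    state$running_var <- (1 - momentum) * state$running_var + momentum * v
  } else {
    mu <- state$running_mean
    v <- state$running_var
    xc <- sweep(xv, 2L, mu)
  }
  istd <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2L, istd, "*")
  out <- sweep(sweep(xhat, 2L, gv, "*"), 2L, bv, "+")
  m <- nrow(xv)
  batch_stats <- training && m > 1L
  ad_node(tape, out, parents = list(x, gamma, beta), backward = function(g) {
    gh <- sweep(g, 2L, gv, "*")
    if (batch_stats) {
      dx <- sweep(gh, 2L, colMeans(gh)) - xhat * rep(colMeans(gh * xhat), each = m)
      dx <- sweep(dx, 2L, istd, "*")
    } else {
      dx <- sweep(gh, 2L, istd, "*")
    }
    list(dx, colSums(g * xhat), colSums(g))
  })
}

## ---- reductions and losses ----

ad_mean <- function(tape, x) {
  xv <- ad_value(x)
  n <- length(xv)
  ad_node(tape, sum(xv) / n, parents = list(x), backward = function(g) {
    list(array(g / n, dim = dim(xv)))
  })
}

ad_sum <- function(tape, x) {
  xv <- ad_value(x)
  ad_node(tape, sum(xv), parents = list(x), backward = function(g) {
    list(array(g, dim = dim(xv)))
  })
}

# mean squared error; pred and target column vectors / matrices of equal shape
ad_loss_mse <- function(tape, pred, target) {
  pv <- ad_value(pred); tv <- ad_value(target)
  d <- pv - tv
  n <- length(d)
  ad_node(tape, sum(d * d) / n, parents = list(pred),
          backward = function(g) list(g * 2 * d / n))
}

# softmax cross-entropy, fused for stability. classes are 1-based indices;
# weight (constant) rescales per-row contributions and the mean divides by
# sum(weight) — used to average residue losses over true (non-pad) lengths.
ad_loss_softmax_ce <- function(tape, logits, classes, weight = NULL) {
  zv <- ad_value(logits)
  n <- nrow(zv)
  if (is.null(weight)) weight <- rep(1, n)
  wsum <- sum(weight)
  m <- apply(zv, 1L, max)
  ex <- exp(zv - m)
  p <- ex / rowSums(ex)
  picked <- zv[cbind(seq_len(n), classes)]
  lse <- m + log(rowSums(ex))
  loss <- sum(weight * (lse - picked)) / wsum
  ad_node(tape, loss, parents = list(logits), backward = function(g) {
    gm <- p
    gm[cbind(seq_len(n), classes)] <- gm[cbind(seq_len(n), classes)] - 1
    list(g * gm * (weight / wsum))
  })
}

# binary cross-entropy on logits (stable softplus form); y in {0,1}
ad_loss_bce_logits <- function(tape, logits, y) {
  zv <- as.vector(ad_value(logits))
  yv <- as.vector(y)
  n <- length(zv)
  loss <- sum(pmax(zv, 0) - zv * yv + log1p(exp(-abs(zv)))) / n
  p <- stats::plogis(zv)
  ad_node(tape, loss, parents = list(logits), backward = function(g) {
    list(matrix(g * (p - yv) / n, ncol = 1L))
  })
}

## ---- extras used by attention and GNN layers ----

ad_exp <- function(tape, x) {
  y <- exp(ad_value(x))
  ad_node(tape, y, parents = list(x), backward = function(g) list(g * y))
}

ad_div <- function(tape, a, b) {
  av <- ad_value(a); bv <- ad_value(b)
  ad_node(tape, av / bv, parents = list(a, b), backward = function(g) {
    list(g / bv, -g * av / (bv * bv))
  })
}

# tile a single-column matrix across k columns
ad_col_rep <- function(tape, x, k) {
  xv <- ad_value(x)
  ad_node(tape, matrix(xv, nrow(xv), k), parents = list(x), backward = function(g) {
    list(matrix(rowSums(g), ncol = 1L))
  })
}

ad_matmul_nt <- function(tape, a, b) {  # a %*% t(b)
  av <- ad_value(a); bv <- ad_value(b)
  ad_node(tape, tcrossprod(av, bv), parents = list(a, b), backward = function(g) {
    list(g %*% bv, crossprod(g, av))
  })
}

ad_cols <- function(tape, x, cols) {
  xv <- ad_value(x)
  ad_node(tape, xv[, cols, drop = FALSE], parents = list(x), backward = function(g) {
    gx <- matrix(0, nrow(xv), ncol(xv))
    gx[, cols] <- g
    list(gx)
  })
}

# Assemble rows from a list of nodes: value[row_idx[[j]], ] <- nodes[[j]]
ad_stack_rows <- function(tape, nodes, row_idx, n_rows) {
  nc <- ncol(ad_value(nodes[[1L]]))
  out <- matrix(0, n_rows, nc)
  for (j in seq_along(nodes)) out[row_idx[[j]], ] <- ad_value(nodes[[j]])
  ad_node(tape, out, parents = nodes, backward = function(g) {
    lapply(row_idx, function(ix) g[ix, , drop = FALSE])
  })
}

ad_reshape <- function(tape, x, nr, nc) {
  xv <- ad_value(x)
  ad_node(tape, matrix(as.vector(xv), nr, nc), parents = list(x),
          backward = function(g) {
            list(matrix(as.vector(g), nrow(xv), ncol(xv)))
          })
}

# fast row-max (max.col is C-level; apply() is too slow in hot paths)
row_max <- function(x) x[cbind(seq_len(nrow(x)), max.col(x, ties.method = "first"))]

# Fused batched multi-head self-attention over B padded sequences of common
# length L. q, k, v are flat (B*L) x d; key_mask is the B x L validity mask.
# One node with one backward avoids per-slice scatter allocations.
ad_mha <- function(tape, q, k, v, B, L, H, key_mask) {
  qv <- ad_value(q); kv <- ad_value(k); vv <- ad_value(v)
  d <- ncol(qv); dk <- d %/% H
  sc <- 1 / sqrt(dk)
  out <- matrix(0, B * L, d)
  attn <- vector("list", B * H)
  for (i in seq_len(B)) {
    rows <- ((i - 1L) * L + 1L):(i * L)
    shift <- rep(ifelse(key_mask[i, ] > 0, 0, -Inf), each = L)
    for (h in seq_len(H)) {
      cols <- ((h - 1L) * dk + 1L):(h * dk)
      S <- tcrossprod(qv[rows, cols, drop = FALSE],
                      kv[rows, cols, drop = FALSE]) * sc + shift
      ex <- exp(S - row_max(S))
      A <- ex / rowSums(ex)
      attn[[(i - 1L) * H + h]] <- A
      out[rows, cols] <- A %*% vv[rows, cols, drop = FALSE]
    }
  }
  ad_node(tape, out, parents = list(q, k, v), backward = function(g) {
    gq <- matrix(0, B * L, d); gk <- matrix(0, B * L, d)
    gv <- matrix(0, B * L, d)
    for (i in seq_len(B)) {
      rows <- ((i - 1L) * L + 1L):(i * L)
      for (h in seq_len(H)) {
        cols <- ((h - 1L) * dk + 1L):(h * dk)
        A <- attn[[(i - 1L) * H + h]]
        go <- g[rows, cols, drop = FALSE]
        gv[rows, cols] <- crossprod(A, go)
        gA <- tcrossprod(go, vv[rows, cols, drop = FALSE])
        gS <- (gA - rowSums(gA * A)) * A * sc
        gq[rows, cols] <- gS %*% kv[rows, cols, drop = FALSE]
        gk[rows, cols] <- crossprod(gS, qv[rows, cols, drop = FALSE])
      }
    }
    list(gq, gk, gv)
  })
}
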
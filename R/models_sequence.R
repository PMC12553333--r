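# Forward passes of the sequence-based architectures.
#
# Layout convention: a padded batch of B sequences of (common) length L is a
# flat (B*L) x d matrix whose row (i-1)*L + l is position l of sample i.
# Pad positions are zeroed after every layer so batch composition never
# leaks into valid outputs.

# Source-row indices for a same-padded 1-D convolution of kernel K.
.conv_idx_cache <- new.env(parent = emptyenv())

conv_idx <- function(B, L, K) {
  key <- paste(B, L, K, sep = "_")
  hit <- .conv_idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  idx <- conv_idx_build(B, L, K)
  .conv_idx_cache[[key]] <- idx
  idx
}

conv_idx_build <- function(B, L, K) {
  left <- (K - 1L) %/% 2L
  pos <- matrix(0L, L, K)
  for (k in seq_len(K)) {
    src <- seq_len(L) + (k - 1L) - left
    src[src < 1L | src > L] <- 0L
    pos[, k] <- src
  }
  idx <- matrix(0L, B * L, K)
  for (i in seq_len(B)) {
    block <- pos
    block[block > 0L] <- block[block > 0L] + (i - 1L) * L
    idx[((i - 1L) * L + 1L):(i * L), ] <- block
  }
  idx
}

# mask as a flat 0/1 vector aligned with the (B*L) row layout
flat_mask <- function(batch) as.numeric(t(batch$mask))

seq_sample_of_row <- function(B, L) rep(seq_len(B), each = L)

# masked global pooling of a flat node -> B x d
pool_max_masked <- function(tape, x, batch) {
  B <- nrow(batch$mask); L <- ncol(batch$mask)
  valid <- which(flat_mask(batch) > 0)
  xv <- ad_rows(tape, x, valid)
  ad_segment_max(tape, xv, seq_sample_of_row(B, L)[valid], B)
}

pool_mean_masked <- function(tape, x, batch) {
  B <- nrow(batch$mask); L <- ncol(batch$mask)
  s <- ad_segment_sum(tape, ad_row_scale(tape, x, flat_mask(batch)),
                      seq_sample_of_row(B, L), B)
  ad_row_scale(tape, s, 1 / batch$lengths)
}

# three convolutional stages (filters 32/64/96, kernels 4/8/12), ReLU,
# dropout, pad rows re-zeroed after each stage
cnn_stages <- function(tape, P, cfg, batch, training) {
  B <- nrow(batch$mask); L <- ncol(batch$mask)
  m <- flat_mask(batch)
  X <- one_hot_flat(batch)
  h <- ad_leaf(tape, X)
  for (i in seq_along(cfg$conv_filters)) {
    idx <- conv_idx(B, L, cfg$conv_kernels[i])
    cols <- ad_im2col(tape, h, idx)
    h <- ad_relu(tape, ad_linear(tape, cols, P[[paste0("conv", i, "_W")]],
                                 P[[paste0("conv", i, "_b")]]))
    h <- ad_dropout(tape, h, cfg$dropout, training)
    h <- ad_row_scale(tape, h, m)
  }
  h
}

# one GRU direction over the flat input; returns flat (B*L) x nh outputs
gru_direction <- function(tape, P, prefix, X, batch, reverse = FALSE) {
  B <- nrow(batch$mask); L <- ncol(batch$mask)
  nh <- length(ad_value(P[[paste0(prefix, "_bz")]]))
  h <- ad_leaf(tape, matrix(0, B, nh))
  steps <- if (reverse) rev(seq_len(L)) else seq_len(L)
  outs <- vector("list", L)
  for (t in steps) {
    rows_t <- (seq_len(B) - 1L) * L + t
    xt <- ad_rows(tape, X, rows_t)
    z <- ad_sigmoid(tape, ad_add(tape,
           ad_linear(tape, xt, P[[paste0(prefix, "_Wz")]], P[[paste0(prefix, "_bz")]]),
           ad_matmul(tape, h, P[[paste0(prefix, "_Uz")]])))
    r <- ad_sigmoid(tape, ad_add(tape,
           ad_linear(tape, xt, P[[paste0(prefix, "_Wr")]], P[[paste0(prefix, "_br")]]),
           ad_matmul(tape, h, P[[paste0(prefix, "_Ur")]])))
    hh <- ad_tanh(tape, ad_add(tape,
            ad_linear(tape, xt, P[[paste0(prefix, "_Wh")]], P[[paste0(prefix, "_bh")]]),
            ad_matmul(tape, ad_hadamard(tape, r, h), P[[paste0(prefix, "_Uh")]])))
    hnew <- ad_add(tape, h, ad_hadamard(tape, z, ad_sub(tape, hh, h)))
    mt <- matrix(batch$mask[, t], B, nh)  # hold state across pad positions
    h <- ad_add(tape, h, ad_hadamard(tape, mt, ad_sub(tape, hnew, h)))
    outs[[t]] <- h
  }
  ad_stack_rows(tape, outs,
                lapply(seq_len(L), function(t) (seq_len(B) - 1L) * L + t),
                B * L)
}

# sinusoidal positional encoding, flat layout
positional_encoding <- function(B, L, d) {
  pos <- seq_len(L) - 1L
  i <- seq_len(d %/% 2) - 1L
  freq <- 1 / 10000^(2 * i / d)
  ang <- outer(pos, freq)
  pe <- matrix(0, L, d)
  pe[, seq(1L, d, by = 2L)] <- sin(ang)
  pe[, seq(2L, d, by = 2L)] <- cos(ang)
  pe[rep(seq_len(L), times = B), , drop = FALSE]
}

transformer_encode <- function(tape, P, cfg, batch, training) {
  B <- nrow(batch$mask); L <- ncol(batch$mask)
  d <- cfg$hidden_dim; H <- cfg$n_heads; dk <- d %/% H
  m <- flat_mask(batch)
  tok <- as.integer(t(batch$token_matrix))
  tok[tok == 0L] <- 1L  # pad rows are zeroed by the mask right after lookup
  # token embeddings are scaled by sqrt(d) so content is not drowned by the
  # unit-amplitude sinusoidal positional encoding (standard practice)
  h <- ad_row_scale(tape, ad_rows(tape, P$embed, tok), m * sqrt(d))
  h <- ad_add(tape, h, positional_encoding(B, L, d) * m)
  for (l in seq_len(cfg$n_layers)) {
    q <- ad_linear(tape, h, P[[sprintf("attn%d_q_W", l)]], P[[sprintf("attn%d_q_b", l)]])
    k <- ad_linear(tape, h, P[[sprintf("attn%d_k_W", l)]], P[[sprintf("attn%d_k_b", l)]])
    v <- ad_linear(tape, h, P[[sprintf("attn%d_v_W", l)]], P[[sprintf("attn%d_v_b", l)]])
    attn <- ad_mha(tape, q, k, v, B, L, H, batch$mask)
    attn <- ad_linear(tape, attn, P[[sprintf("attn%d_o_W", l)]],
                      P[[sprintf("attn%d_o_b", l)]])
    attn <- ad_dropout(tape, attn, cfg$dropout, training)
    h <- ad_add(tape, h, attn)
    # ReLU acts inside the feed-forward sublayer that follows each
    # self-attention layer; LayerNorm closes the block after the MLP
    ff <- ad_relu(tape, ad_linear(tape, h, P[[sprintf("ffn%d_1_W", l)]],
                                  P[[sprintf("ffn%d_1_b", l)]]))
    ff <- ad_dropout(tape, ff, cfg$dropout, training)
    ff <- ad_linear(tape, ff, P[[sprintf("ffn%d_2_W", l)]],
                    P[[sprintf("ffn%d_2_b", l)]])
    h <- ad_layer_norm(tape, ad_add(tape, h, ff),    # LayerNorm after MLP
                       P[[sprintf("ln%d_gamma", l)]], P[[sprintf("ln%d_beta", l)]])
    h <- ad_row_scale(tape, h, m)
  }
  h
}

# Encode one padded batch -> list(rep = B x rep_dim pooled representation,
# per_pos = flat per-position representation used by residue heads)
encode_sequence <- function(tape, model, batch, training) {
  P <- model$.wrapped
  cfg <- model$config
  arch <- model$architecture
  if (arch == "cnn") {
    h <- cnn_stages(tape, P, cfg, batch, training)
    if (model$task$level == "residue") {
      pp <- ad_relu(tape, ad_linear(tape, h, P$fc_W, P$fc_b))
      list(rep = NULL, per_pos = ad_dropout(tape, pp, cfg$dropout, training))
    } else {
      pooled <- pool_max_masked(tape, h, batch)  # MaxPool1d over positions
      rep <- ad_relu(tape, ad_linear(tape, pooled, P$fc_W, P$fc_b))
      list(rep = ad_dropout(tape, rep, cfg$dropout, training), per_pos = NULL)
    }
  } else if (arch == "cnn_gru") {
    h <- cnn_stages(tape, P, cfg, batch, training)
    for (l in seq_len(cfg$n_layers)) {
      fwd <- gru_direction(tape, P, paste0("gru", l, "_fwd"), h, batch, FALSE)
      bwd <- gru_direction(tape, P, paste0("gru", l, "_bwd"), h, batch, TRUE)
      h <- ad_relu(tape, ad_concat_cols(tape, fwd, bwd))
      h <- ad_row_scale(tape, h, flat_mask(batch))
    }
    if (model$task$level == "residue") list(rep = NULL, per_pos = h)
    else list(rep = pool_mean_masked(tape, h, batch), per_pos = NULL)
  } else if (arch == "transformer") {
    h <- transformer_encode(tape, P, cfg, batch, training)
    if (model$task$level == "residue") {
      list(rep = NULL, per_pos = h)
    } else {
      pooled <- if (identical(cfg$pooling, "mean")) {
        pool_mean_masked(tape, h, batch)
      } else {
        pool_max_masked(tape, h, batch)
      }
      list(rep = pooled, per_pos = NULL)
    }
  } else {
    pb_stop("pb_internal", sprintf("'%s' is not a sequence architecture", arch))
  }
}
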
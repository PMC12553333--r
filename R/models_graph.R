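# Forward passes of the structure-based (graph) architectures over batched
# block-diagonal peptide graphs (see batch_graphs()).

# softmax of per-row scores e (n x 1 node) within segments
seg_softmax <- function(tape, e, group, ngroups) {
  m <- ad_segment_max(tape, e, group, ngroups)
  ez <- ad_exp(tape, ad_sub(tape, e, ad_rows(tape, m, group)))
  s <- ad_segment_sum(tape, ez, group, ngroups)
  ad_div(tape, ez, ad_rows(tape, s, group))
}

# degree-normalized propagation weights with self-loops (symmetric GCN rule)
gcn_edges <- function(gb) {
  src <- c(gb$src, seq_len(gb$n_nodes))
  dst <- c(gb$dst, seq_len(gb$n_nodes))
  deg <- tabulate(dst, nbins = gb$n_nodes)
  list(src = src, dst = dst, w = 1 / sqrt(deg[src] * deg[dst]))
}

gcn_layer <- function(tape, H, W, b, ed, n_nodes) {
  HW <- ad_linear(tape, H, W, b)
  msg <- ad_row_scale(tape, ad_rows(tape, HW, ed$src), ed$w)
  ad_segment_sum(tape, msg, ed$dst, n_nodes)
}

graph_readout <- function(tape, P, cfg, H, gid, G) {
  d <- ncol(ad_value(H))
  switch(cfg$readout,
    weighted_sum_max = {
      gate <- ad_sigmoid(tape, ad_linear(tape, H, P$gate_W, P$gate_b))
      ws <- ad_segment_sum(tape, ad_hadamard(tape, H, ad_col_rep(tape, gate, d)),
                           gid, G)
      mx <- ad_segment_max(tape, H, gid, G)
      ad_concat_cols(tape, ws, mx)
    },
    sum_max = ad_concat_cols(tape, ad_segment_sum(tape, H, gid, G),
                             ad_segment_max(tape, H, gid, G)),
    attentive = {  # gated attention pooling
      a <- seg_softmax(tape, ad_linear(tape, H, P$ro_att_W, P$ro_att_b), gid, G)
      c <- ad_tanh(tape, ad_linear(tape, H, P$ro_ctx_W, P$ro_ctx_b))
      ad_segment_sum(tape, ad_hadamard(tape, c, ad_col_rep(tape, a, d)), gid, G)
    },
    max = ad_segment_max(tape, H, gid, G))
}

act_fn <- function(cfg) {
  if (identical(cfg$activation, "leaky_relu")) {
    function(tape, x) ad_leaky_relu(tape, x)
  } else {
    function(tape, x) ad_relu(tape, x)
  }
}

# shortest-path data per graph for PAGTN / Graphormer: pair list up to
# `hops`, hop distance, and summed bond features along one shortest path
graph_path_features <- function(g, hops) {
  eb <- featurize_bonds(g)
  n <- g$n_atoms
  adj <- split(seq_along(eb$src), eb$src)  # edge ids by source
  pairs_src <- integer(0); pairs_dst <- integer(0)
  pairs_hop <- integer(0); feat <- NULL
  for (s in seq_len(n)) {
    depth <- rep(NA_integer_, n); depth[s] <- 0L
    fsum <- matrix(0, n, 3L)
    frontier <- s
    for (h in seq_len(hops)) {
      nxt <- integer(0)
      for (u in frontier) {
        for (eid in adj[[as.character(u)]]) {
          v <- eb$dst[eid]
          if (is.na(depth[v])) {
            depth[v] <- h
            fsum[v, ] <- fsum[u, ] + eb$features[eid, ]
            nxt <- c(nxt, v)
          }
        }
      }
      if (length(nxt) == 0L) break
      frontier <- nxt
    }
    reach <- which(!is.na(depth) & depth > 0L)
    pairs_src <- c(pairs_src, rep.int(s, length(reach)))
    pairs_dst <- c(pairs_dst, reach)
    pairs_hop <- c(pairs_hop, depth[reach])
    feat <- rbind(feat, fsum[reach, , drop = FALSE])
  }
  hop1 <- matrix(0, length(pairs_hop), hops)
  hop1[cbind(seq_along(pairs_hop), pairs_hop)] <- 1
  list(src = pairs_src, dst = pairs_dst, hop = pairs_hop,
       features = cbind(feat, hop1))
}

encode_graph <- function(tape, model, gb, training) {
  P <- model$.wrapped
  cfg <- model$config
  arch <- model$architecture
  act <- act_fn(cfg)
  N <- gb$n_nodes; G <- gb$n_graphs
  gid <- gb$node_graph
  d <- cfg$hidden_dim

  frozen <- model$frozen
  proj <- function(Pset) ad_relu(tape, ad_linear(tape, ad_leaf(tape, gb$H),
                                                 Pset$proj_W, Pset$proj_b))

  H <- NULL
  if (arch %in% c("gcn", "neuralfp")) {
    Pset <- if (arch == "neuralfp") frozen else P
    ed <- gcn_edges(gb)
    H <- proj(Pset)
    for (l in seq_len(cfg$n_layers)) {
      H <- act(tape, gcn_layer(tape, H, Pset[[paste0("layer", l, "_W")]],
                               Pset[[paste0("layer", l, "_b")]], ed, N))
      if (arch == "gcn") H <- ad_dropout(tape, H, cfg$dropout, training)
    }
  } else if (arch == "gat") {
    src <- c(gb$src, seq_len(N)); dst <- c(gb$dst, seq_len(N))
    hd <- d %/% cfg$n_heads
    H <- proj(P)
    for (l in seq_len(cfg$n_layers)) {
      pre <- paste0("layer", l)
      Wh <- ad_matmul(tape, H, P[[paste0(pre, "_W")]])
      heads <- vector("list", cfg$n_heads)
      for (h in seq_len(cfg$n_heads)) {
        cols <- ((h - 1L) * hd + 1L):(h * hd)
        Whh <- ad_cols(tape, Wh, cols)
        ssrc <- ad_matmul(tape, Whh, ad_cols(tape, P[[paste0(pre, "_asrc")]], h))
        sdst <- ad_matmul(tape, Whh, ad_cols(tape, P[[paste0(pre, "_adst")]], h))
        e <- ad_leaky_relu(tape, ad_add(tape, ad_rows(tape, ssrc, src),
                                        ad_rows(tape, sdst, dst)), alpha = 0.2)
        alpha <- seg_softmax(tape, e, dst, N)
        msg <- ad_hadamard(tape, ad_rows(tape, Whh, src),
                           ad_col_rep(tape, alpha, hd))
        heads[[h]] <- ad_segment_sum(tape, msg, dst, N)
      }
      Hn <- heads[[1L]]
      for (h in seq_len(cfg$n_heads)[-1L]) Hn <- ad_concat_cols(tape, Hn, heads[[h]])
      H <- act(tape, Hn)
    }
  } else if (arch == "mpnn") {
    H <- proj(P)
    for (l in seq_len(cfg$n_layers)) {
      pre <- paste0("layer", l)
      min_ <- ad_concat_cols(tape, ad_rows(tape, H, gb$src), gb$edge_features)
      msg <- ad_relu(tape, ad_linear(tape, min_, P[[paste0(pre, "_msg_W")]],
                                     P[[paste0(pre, "_msg_b")]]))
      mv <- ad_segment_sum(tape, msg, gb$dst, N)
      H <- ad_relu(tape, ad_linear(tape, ad_concat_cols(tape, H, mv),
                                   P[[paste0(pre, "_upd_W")]],
                                   P[[paste0(pre, "_upd_b")]]))
    }
  } else if (arch == "attentivefp") {
    H <- proj(P)
    for (l in seq_len(cfg$n_layers)) {
      pre <- paste0("layer", l)
      C <- ad_matmul(tape, H, P[[paste0(pre, "_ctx_W")]])
      ain <- ad_concat_cols(tape,
               ad_concat_cols(tape, ad_rows(tape, H, gb$dst),
                              ad_rows(tape, H, gb$src)),
               gb$edge_features)
      e <- ad_leaky_relu(tape, ad_linear(tape, ain, P[[paste0(pre, "_att_W")]],
                                         P[[paste0(pre, "_att_b")]]), alpha = 0.2)
      alpha <- seg_softmax(tape, e, gb$dst, N)
      ctx <- ad_segment_sum(tape, ad_hadamard(tape, ad_rows(tape, C, gb$src),
                                              ad_col_rep(tape, alpha, d)),
                            gb$dst, N)
      # GRU-cell update with the attended context as input
      gp <- paste0(pre, "_gru")
      z <- ad_sigmoid(tape, ad_add(tape,
             ad_linear(tape, ctx, P[[paste0(gp, "_Wz")]], P[[paste0(gp, "_bz")]]),
             ad_matmul(tape, H, P[[paste0(gp, "_Uz")]])))
      r <- ad_sigmoid(tape, ad_add(tape,
             ad_linear(tape, ctx, P[[paste0(gp, "_Wr")]], P[[paste0(gp, "_br")]]),
             ad_matmul(tape, H, P[[paste0(gp, "_Ur")]])))
      hh <- ad_tanh(tape, ad_add(tape,
              ad_linear(tape, ctx, P[[paste0(gp, "_Wh")]], P[[paste0(gp, "_bh")]]),
              ad_matmul(tape, ad_hadamard(tape, r, H), P[[paste0(gp, "_Uh")]])))
      H <- ad_add(tape, H, ad_hadamard(tape, z, ad_sub(tape, hh, H)))
    }
  } else if (arch == "pagtn") {
    paths <- lapply(gb$graphs, graph_path_features, hops = cfg$path_hops)
    offs <- cumsum(c(0L, vapply(gb$graphs, function(g) g$n_atoms, integer(1L))))
    src <- integer(0); dst <- integer(0); pf <- NULL
    for (i in seq_along(paths)) {
      src <- c(src, paths[[i]]$src + offs[i])
      dst <- c(dst, paths[[i]]$dst + offs[i])
      pf <- rbind(pf, paths[[i]]$features)
    }
    src <- c(src, seq_len(N)); dst <- c(dst, seq_len(N))
    pf <- rbind(pf, matrix(0, N, ncol(pf)))  # self pairs, zero path features
    H <- proj(P)
    for (l in seq_len(cfg$n_layers)) {
      pre <- paste0("layer", l)
      Wh <- ad_matmul(tape, H, P[[paste0(pre, "_W")]])
      ssrc <- ad_matmul(tape, Wh, P[[paste0(pre, "_asrc")]])
      sdst <- ad_matmul(tape, Wh, P[[paste0(pre, "_adst")]])
      pscore <- ad_matmul(tape, ad_leaf(tape, pf), P[[paste0(pre, "_apath")]])
      e <- ad_leaky_relu(tape, ad_add(tape,
             ad_add(tape, ad_rows(tape, ssrc, src), ad_rows(tape, sdst, dst)),
             pscore), alpha = 0.2)
      alpha <- seg_softmax(tape, e, dst, N)
      msg <- ad_hadamard(tape, ad_rows(tape, Wh, src), ad_col_rep(tape, alpha, d))
      H <- act(tape, ad_segment_sum(tape, msg, dst, N))
    }
  } else if (arch == "graphormer") {
    deg <- tabulate(c(gb$src), nbins = N)  # directed copies = undirected degree
    H <- ad_add(tape, ad_linear(tape, ad_leaf(tape, gb$H), P$proj_W, P$proj_b),
                ad_rows(tape, P$degree_embed, pmin(deg, 4L)))
    hN <- cfg$n_heads; dk <- d %/% hN
    offs <- cumsum(c(0L, vapply(gb$graphs, function(g) g$n_atoms, integer(1L))))
    spd_list <- lapply(gb$graphs, function(g) {
      ig <- igraph::graph_from_edgelist(cbind(g$bonds$from, g$bonds$to),
                                        directed = FALSE)
      pmin(igraph::distances(ig), cfg$max_spd)
    })
    ebias_const <- lapply(seq_along(gb$graphs), function(i) {
      g <- gb$graphs[[i]]
      n <- g$n_atoms
      eb <- featurize_bonds(g)
      M <- matrix(0, n * n, 3L)
      M[(eb$dst - 1L) * n + eb$src, ] <- eb$features
      M
    })
    for (l in seq_len(cfg$n_layers)) {
      pre <- paste0("layer", l)
      q <- ad_linear(tape, H, P[[paste0(pre, "_q_W")]], P[[paste0(pre, "_q_b")]])
      k <- ad_linear(tape, H, P[[paste0(pre, "_k_W")]], P[[paste0(pre, "_k_b")]])
      v <- ad_linear(tape, H, P[[paste0(pre, "_v_W")]], P[[paste0(pre, "_v_b")]])
      per_graph <- vector("list", G)
      rows_list <- vector("list", G)
      for (i in seq_len(G)) {
        rows <- (offs[i] + 1L):offs[i + 1L]
        rows_list[[i]] <- rows
        n <- length(rows)
        spd_flat <- as.vector(spd_list[[i]]) + 1L
        spd_g <- ad_rows(tape, P$spd_bias, spd_flat)        # n^2 x heads
        edge_g <- ad_matmul(tape, ad_leaf(tape, ebias_const[[i]]), P$edge_bias)
        bias <- ad_add(tape, spd_g, edge_g)
        qi <- ad_rows(tape, q, rows); ki <- ad_rows(tape, k, rows)
        vi <- ad_rows(tape, v, rows)
        heads <- vector("list", hN)
        for (h in seq_len(hN)) {
          cols <- ((h - 1L) * dk + 1L):(h * dk)
          s <- ad_scale(tape, ad_matmul_nt(tape, ad_cols(tape, qi, cols),
                                           ad_cols(tape, ki, cols)), 1 / sqrt(dk))
          s <- ad_add(tape, s, ad_reshape(tape, ad_cols(tape, bias, h), n, n))
          a <- ad_softmax_rows(tape, s)
          heads[[h]] <- ad_matmul(tape, a, ad_cols(tape, vi, cols))
        }
        ha <- heads[[1L]]
        for (h in seq_len(hN)[-1L]) ha <- ad_concat_cols(tape, ha, heads[[h]])
        per_graph[[i]] <- ha
      }
      attn <- ad_stack_rows(tape, per_graph, rows_list, N)
      attn <- ad_linear(tape, attn, P[[paste0(pre, "_o_W")]],
                        P[[paste0(pre, "_o_b")]])
      H <- ad_relu(tape, ad_add(tape, H, attn))
      ff <- ad_relu(tape, ad_linear(tape, H, P[[paste0(pre, "_ffn1_W")]],
                                    P[[paste0(pre, "_ffn1_b")]]))
      ff <- ad_linear(tape, ff, P[[paste0(pre, "_ffn2_W")]],
                      P[[paste0(pre, "_ffn2_b")]])
      H <- ad_layer_norm(tape, ad_add(tape, H, ff),
                         P[[paste0(pre, "_ln_gamma")]],
                         P[[paste0(pre, "_ln_beta")]])
    }
  }

  ro <- graph_readout(tape, P, cfg, H, gid, G)
  rep <- ad_linear(tape, ro, P$mlp1_W, P$mlp1_b)
  if (!is.null(model$state$bn_mlp1)) {
    rep <- ad_batch_norm(tape, rep, P$bn_mlp1_gamma, P$bn_mlp1_beta,
                         model$state$bn_mlp1, training)
  }
  rep <- act(tape, rep)
  if (model$architecture == "neuralfp") {
    rep <- ad_linear(tape, rep, P$mlp2_W, P$mlp2_b)
    if (!is.null(model$state$bn_mlp2)) {
      rep <- ad_batch_norm(tape, rep, P$bn_mlp2_gamma, P$bn_mlp2_beta,
                           model$state$bn_mlp2, training)
    }
    rep <- act(tape, rep)
  }
  ad_dropout(tape, rep, cfg$dropout, training)
}
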
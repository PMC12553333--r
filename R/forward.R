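# Uniform forward contract over all architectures.
#
# Output shape is a pure function of the task: regression -> (B, 1) scores,
# single-sequence classification -> (B, C) softmax logits, pair binary ->
# (B, 1) sigmoid logits, residue tasks -> flat (B*L, C) per-position logits
# (pad rows carry no loss and no metric weight).

#' Fixed per-sequence embedding providers
#'
#' An embedding provider maps a protein sequence to a fixed-length numeric
#' vector and is never trained: only the downstream head learns. Three
#' deterministic providers are shipped: `"kmer"` (counts of all canonical
#' k-mers, dimension `20^k`), `"composition"` (20-dim amino-acid fractions),
#' and `"random"` (a hash-seeded pseudo-random vector per sequence — carries
#' no signal, useful for negative controls and frozen-contract tests).
#'
#' @param type Provider family.
#' @param k k-mer size for the `"kmer"` provider.
#' @param dim Output dimension for the `"random"` provider.
#' @param seed Base seed for the `"random"` provider.
#' @return A `pb_provider`: `name`, `dimension`, and a memoised `lookup`
#'   function (the same sequence always yields the identical vector).
#' @export
embedding_provider <- function(type = c("kmer", "composition", "random"),
                               k = 2L, dim = 64L, seed = 1L) {
  type <- match.arg(type)
  cache <- new.env(parent = emptyenv())
  if (type == "kmer") {
    kmers <- AA_CANONICAL
    if (k > 1L) for (i in seq_len(k - 1L)) {
      kmers <- as.vector(outer(kmers, AA_CANONICAL, paste0))
    }
    kmap <- stats::setNames(seq_along(kmers), kmers)
    dimension <- length(kmers)
    lookup <- function(sequence) {
      key <- sequence
      if (!is.null(cache[[key]])) return(cache[[key]])
      ch <- strsplit(toupper(sequence), "")[[1L]]
      v <- numeric(dimension)
      if (length(ch) >= k) {
        subs <- vapply(seq_len(length(ch) - k + 1L), function(i)
          paste(ch[i:(i + k - 1L)], collapse = ""), "")
        tab <- table(kmap[subs])  # k-mers containing X drop out as NA
        v[as.integer(names(tab))] <- as.numeric(tab)
      }
      cache[[key]] <- v
      v
    }
  } else if (type == "composition") {
    dimension <- 20L
    lookup <- function(sequence) {
      ch <- strsplit(toupper(sequence), "")[[1L]]
      tabulate(match(ch, AA_CANONICAL), nbins = 20L) / length(ch)
    }
  } else {
    dimension <- as.integer(dim)
    lookup <- function(sequence) {
      key <- sequence
      if (!is.null(cache[[key]])) return(cache[[key]])
      h <- sum(utf8ToInt(sequence) * seq_len(nchar(sequence))) %% 2147483123L
      v <- with_pb_seed(h + seed, stats::rnorm(dimension))
      cache[[key]] <- v
      v
    }
  }
  structure(list(name = paste0(type, if (type == "kmer") k else ""),
                 dimension = dimension, lookup = lookup),
            class = "pb_provider")
}

# Precompute per-record features for a model; returns a collator closure.
prepare_inputs <- function(model, records, max_length = 300L) {
  arch <- model$architecture
  pair <- model$task$arity == "pair"
  get_seqs <- function(side) {
    vapply(records, function(r) {
      if (pair) (if (side == 1L) r$sequence_a else r$sequence_b) else r$sequence
    }, "")
  }
  if (arch %in% PB_SEQ_ARCHS) {
    tok_a <- lapply(get_seqs(1L), tokenize, max_length = max_length)
    tok_b <- if (pair) lapply(get_seqs(2L), tokenize, max_length = max_length)
    function(idx) {
      if (pair) list(a = pad_and_mask(tok_a[idx]), b = pad_and_mask(tok_b[idx]))
      else pad_and_mask(tok_a[idx])
    }
  } else if (arch %in% PB_GRAPH_ARCHS) {
    gr_a <- lapply(get_seqs(1L), sequence_to_peptide_graph)
    gr_b <- if (pair) lapply(get_seqs(2L), sequence_to_peptide_graph)
    function(idx) {
      if (pair) list(a = batch_graphs(gr_a[idx]), b = batch_graphs(gr_b[idx]))
      else batch_graphs(gr_a[idx])
    }
  } else {  # fixed_embedding: provider vectors, computed once, frozen
    emb_a <- do.call(rbind, lapply(get_seqs(1L), model$provider$lookup))
    emb_b <- if (pair) do.call(rbind, lapply(get_seqs(2L), model$provider$lookup))
    function(idx) {
      if (pair) list(a = emb_a[idx, , drop = FALSE], b = emb_b[idx, , drop = FALSE])
      else emb_a[idx, , drop = FALSE]
    }
  }
}

encode_any <- function(tape, model, input, training) {
  arch <- model$architecture
  if (arch %in% PB_SEQ_ARCHS) {
    encode_sequence(tape, model, input, training)
  } else if (arch %in% PB_GRAPH_ARCHS) {
    list(rep = encode_graph(tape, model, input, training), per_pos = NULL)
  } else {
    # standardize provider features with training-split statistics when the
    # model has been (or is being) trained; see train()
    if (!is.null(model$state$feat_mean)) {
      fm <- model$state$feat_mean
      fs <- model$state$feat_sd
      if (length(fm) < ncol(input)) {  # pair: same stats on both halves
        fm <- rep(fm, 2L)
        fs <- rep(fs, 2L)
      }
      input <- sweep(sweep(input, 2L, fm), 2L, fs, "/")
    }
    rep <- ad_relu(tape, ad_linear(tape, ad_leaf(tape, input),
                                   model$.wrapped$mlp1_W, model$.wrapped$mlp1_b))
    rep <- ad_dropout(tape, rep, model$config$dropout, training)
    rep <- ad_relu(tape, ad_linear(tape, rep, model$.wrapped$mlp2_W,
                                   model$.wrapped$mlp2_b))
    list(rep = ad_dropout(tape, rep, model$config$dropout, training),
         per_pos = NULL)
  }
}

# Full forward pass. `input` comes from the prepare_inputs() collator.
# Returns list(out = output node, tape, wrapped = parameter nodes).
pb_forward <- function(model, input, training = FALSE) {
  tape <- ad_tape()
  wrapped <- lapply(model$params, function(p) ad_leaf(tape, p))
  model$.wrapped <- wrapped
  P <- wrapped
  if (model$task$arity == "pair") {
    if (model$architecture == "fixed_embedding") {
      # provider vectors are concatenated before the MLP head
      enc <- encode_any(tape, model, cbind(input$a, input$b), training)
      rep <- enc$rep
    } else {
      ea <- encode_any(tape, model, input$a, training)
      eb <- encode_any(tape, model, input$b, training)
      rep <- ad_concat_cols(tape, ea$rep, eb$rep) # (X_i || X_j), order as given
    }
    out <- ad_linear(tape, rep, P$head_W, P$head_b)
  } else if (model$task$level == "residue") {
    enc <- encode_any(tape, model, input, training)
    out <- ad_linear(tape, enc$per_pos, P$head_W, P$head_b)
  } else {
    enc <- encode_any(tape, model, input, training)
    out <- ad_linear(tape, enc$rep, P$head_W, P$head_b)
  }
  if (any(!is.finite(ad_value(out)))) {
    pb_stop("pb_nonfinite", "non-finite values in forward pass output")
  }
  list(out = out, tape = tape, wrapped = wrapped)
}
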
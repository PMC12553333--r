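# The model zoo: ten trainable architectures plus a fixed-embedding head,
# each carrying its library default configuration.
#
# Sequence-based encoders (cnn, cnn_gru, transformer) consume padded token
# batches; structure-based encoders (gcn, gat, mpnn, neuralfp, attentivefp,
# pagtn, graphormer) consume batched peptide molecular graphs; the
# fixed_embedding head consumes frozen per-sequence vectors from an
# EmbeddingProvider. All models share one forward contract determined by the
# task: regression -> one value per sample, classification -> class logits,
# residue tasks -> per-position logits.

PB_ARCHITECTURES <- c("cnn", "cnn_gru", "transformer", "gcn", "gat", "mpnn",
                      "neuralfp", "attentivefp", "pagtn", "graphormer",
                      "fixed_embedding")
PB_SEQ_ARCHS <- c("cnn", "cnn_gru", "transformer")
PB_GRAPH_ARCHS <- c("gcn", "gat", "mpnn", "neuralfp", "attentivefp",
                    "pagtn", "graphormer")

#' Default model configuration
#'
#' Returns the shipped baseline configuration for an architecture: learning
#' rate (1e-4 for sequence-based and fixed-embedding models, 1e-5 for
#' structure-based), dropout 0.1, layer counts, hidden dimensions, attention
#' heads, activation, normalization, and pooling/readout. The CNN uses three
#' convolutional stages with 32/64/96 filters and kernel sizes 4/8/12 and a
#' 256-wide hidden layer with max pooling over positions.
#'
#' @param architecture One of `r paste0('"', PB_ARCHITECTURES, '"', collapse = ", ")`.
#' @return A `pb_model_config` list.
#' @export
model_config <- function(architecture = PB_ARCHITECTURES) {
  architecture <- match.arg(architecture)
  base <- list(architecture = architecture, dropout = 0.1,
               activation = "relu", n_heads = NA_integer_, norm = "none",
               batch_size = 32L, max_epochs = 100L,
               conv_filters = NA, conv_kernels = NA, readout = NA_character_)
  over <- switch(architecture,
    cnn = list(learning_rate = 1e-4, n_layers = 3L, hidden_dim = 256L,
               pooling = "max", conv_filters = c(32L, 64L, 96L),
               conv_kernels = c(4L, 8L, 12L)),
    cnn_gru = list(learning_rate = 1e-4, n_layers = 2L, hidden_dim = 64L,
                   pooling = "mean", conv_filters = c(32L, 64L, 96L),
                   conv_kernels = c(4L, 8L, 12L)),
    transformer = list(learning_rate = 1e-4, n_layers = 2L, hidden_dim = 64L,
                       n_heads = 4L, norm = "layer", pooling = "max",
                       ffn_dim = 128L),
    gcn = list(learning_rate = 1e-5, n_layers = 3L, hidden_dim = 64L,
               readout = "weighted_sum_max", norm = "batch"),
    gat = list(learning_rate = 1e-5, n_layers = 3L, hidden_dim = 64L,
               n_heads = 4L, readout = "weighted_sum_max"),
    mpnn = list(learning_rate = 1e-5, n_layers = 6L, hidden_dim = 64L,
                readout = "sum_max"),
    neuralfp = list(learning_rate = 1e-5, n_layers = 3L, hidden_dim = 64L,
                    readout = "sum_max", norm = "batch"),
    attentivefp = list(learning_rate = 1e-5, n_layers = 3L, hidden_dim = 64L,
                       readout = "attentive"),
    pagtn = list(learning_rate = 1e-5, n_layers = 5L, hidden_dim = 64L,
                 activation = "leaky_relu", readout = "weighted_sum_max",
                 path_hops = 3L),
    graphormer = list(learning_rate = 1e-5, n_layers = 1L, hidden_dim = 64L,
                      n_heads = 8L, norm = "layer", readout = "max",
                      ffn_dim = 128L, max_spd = 5L),
    # head-only training on frozen features tolerates a larger step size
    # and benefits from a wide hidden layer (matches the CNN's 256)
    fixed_embedding = list(learning_rate = 1e-3, n_layers = 2L,
                           hidden_dim = 256L))
  cfg <- utils::modifyList(base, over)
  if (is.null(cfg$pooling)) cfg$pooling <- NA_character_
  structure(cfg, class = "pb_model_config")
}

#' Dump the default configuration of every architecture
#'
#' One row per architecture with the headline settings; used for
#' golden-file comparison and by the CLI `--arch` inspection flag.
#'
#' @return A data.frame.
#' @export
dump_default_configs <- function() {
  rows <- lapply(PB_ARCHITECTURES, function(a) {
    cfg <- model_config(a)
    pip <- function(x) if (all(is.na(x))) "" else paste(x, collapse = "|")
    pool <- if (!is.na(cfg$readout)) cfg$readout else
      if (!is.null(cfg$pooling) && !is.na(cfg$pooling)) cfg$pooling else ""
    data.frame(architecture = a, learning_rate = cfg$learning_rate,
               dropout = cfg$dropout, activation = cfg$activation,
               n_heads = cfg$n_heads, n_layers = cfg$n_layers,
               hidden_dim = cfg$hidden_dim, pooling = pool,
               batch_size = cfg$batch_size, max_epochs = cfg$max_epochs,
               norm = cfg$norm, conv_filters = pip(cfg$conv_filters),
               conv_kernels = pip(cfg$conv_kernels))
  })
  do.call(rbind, rows)
}

# uniform fan-in initialization
init_mat <- function(nr, nc, fan_in = nr) {
  matrix(stats::runif(nr * nc, -1, 1) / sqrt(fan_in), nr, nc)
}

pb_out_dim <- function(task) {
  switch(task$objective,
    regression = 1L,
    binary = if (task$arity == "pair") 1L else 2L,  # pair: sigmoid; single: softmax
    multiclass = task$num_classes)
}

# per-position class count for residue tasks
pb_residue_classes <- function(task) task$num_classes

#' Construct a predictor model
#'
#' Builds the named architecture with seeded uniform fan-in initialization.
#' Graph and fixed-embedding architectures refuse residue-level tasks
#' (residue prediction is supported by the sequence architectures only).
#'
#' @param architecture Architecture name (see [model_config()]).
#' @param task A [task_spec()].
#' @param config A `pb_model_config`; defaults to [model_config()] for the
#'   architecture.
#' @param seed Integer seed for weight initialization.
#' @param provider An [embedding_provider()], required for
#'   `architecture = "fixed_embedding"`.
#' @return A `pb_model`.
#' @export
build_model <- function(architecture, task, config = model_config(architecture),
                        seed = 1L, provider = NULL) {
  architecture <- match.arg(architecture, PB_ARCHITECTURES)
  stopifnot(inherits(task, "pb_task_spec"))
  if (task$level == "residue" && !(architecture %in% PB_SEQ_ARCHS)) {
    pb_stop("pb_incompatible_architecture", sprintf(
      "architecture '%s' does not support residue-level tasks", architecture))
  }
  if (architecture == "fixed_embedding" && is.null(provider)) {
    pb_stop("pb_missing_provider",
            "fixed_embedding models need an embedding provider")
  }
  params <- with_pb_seed(seed, pb_init_params(architecture, task, config, provider))
  state <- new.env(parent = emptyenv())
  for (nm in names(params$bn_dims)) {
    st <- new.env(parent = emptyenv())
    st$running_mean <- rep(0, params$bn_dims[[nm]])
    st$running_var <- rep(1, params$bn_dims[[nm]])
    state[[nm]] <- st
  }
  structure(list(architecture = architecture, task = task, config = config,
                 params = params$trainable, frozen = params$frozen,
                 state = state, provider = provider,
                 init_seed = as.integer(seed)),
            class = "pb_model")
}

#' @export
print.pb_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, integer(1L)))
  cat(sprintf("<pb_model %s> task '%s' (%s/%s/%s), %d trainable parameters\n",
              x$architecture, x$task$name, x$task$arity, x$task$level,
              x$task$objective, np))
  invisible(x)
}

# Parameter builder. Returns list(trainable =, frozen =, bn_dims =).
pb_init_params <- function(arch, task, cfg, provider) {
  p <- list(); frozen <- list(); bn <- list()
  d <- cfg$hidden_dim
  out_dim <- pb_out_dim(task)
  rep_dim <- NULL

  add_lin <- function(prefix, nin, nout, bias = TRUE) {
    p[[paste0(prefix, "_W")]] <<- init_mat(nin, nout)
    if (bias) p[[paste0(prefix, "_b")]] <<- rep(0, nout)
  }
  add_gru <- function(prefix, nin, nh) {
    for (g in c("z", "r", "h")) {
      p[[paste0(prefix, "_W", g)]] <<- init_mat(nin, nh)
      p[[paste0(prefix, "_U", g)]] <<- init_mat(nh, nh)
      p[[paste0(prefix, "_b", g)]] <<- rep(0, nh)
    }
  }
  add_convs <- function() {
    nin <- 21L
    for (i in seq_along(cfg$conv_filters)) {
      add_lin(paste0("conv", i), cfg$conv_kernels[i] * nin, cfg$conv_filters[i])
      nin <- cfg$conv_filters[i]
    }
    nin
  }

  if (arch == "cnn") {
    cdim <- add_convs()
    add_lin("fc", cdim, d)
    rep_dim <- d
  } else if (arch == "cnn_gru") {
    cdim <- add_convs()
    nin <- cdim
    for (l in seq_len(cfg$n_layers)) {
      add_gru(paste0("gru", l, "_fwd"), nin, d)
      add_gru(paste0("gru", l, "_bwd"), nin, d)
      nin <- 2L * d
    }
    rep_dim <- 2L * d
  } else if (arch == "transformer") {
    p$embed <- init_mat(21L, d, fan_in = 1) * 0.5  # token embedding table
    for (l in seq_len(cfg$n_layers)) {
      for (m in c("q", "k", "v", "o")) add_lin(sprintf("attn%d_%s", l, m), d, d)
      add_lin(sprintf("ffn%d_1", l), d, cfg$ffn_dim)
      add_lin(sprintf("ffn%d_2", l), cfg$ffn_dim, d)
      p[[sprintf("ln%d_gamma", l)]] <- rep(1, d)
      p[[sprintf("ln%d_beta", l)]] <- rep(0, d)
    }
    rep_dim <- d
  } else if (arch %in% PB_GRAPH_ARCHS) {
    node_in <- 5L  # palette {C,N,O,S} one-hot + scaled degree
    edge_in <- 3L  # bond order one-hot
    add_lin("proj", node_in, d)
    layer_params <- function() {
      for (l in seq_len(cfg$n_layers)) {
        pre <- paste0("layer", l)
        if (arch %in% c("gcn", "neuralfp")) {
          add_lin(pre, d, d)
        } else if (arch == "gat") {
          hd <- d %/% cfg$n_heads
          add_lin(pre, d, d, bias = FALSE)
          p[[paste0(pre, "_asrc")]] <<- init_mat(hd, cfg$n_heads)
          p[[paste0(pre, "_adst")]] <<- init_mat(hd, cfg$n_heads)
        } else if (arch == "mpnn") {
          add_lin(paste0(pre, "_msg"), d + edge_in, d)
          add_lin(paste0(pre, "_upd"), 2L * d, d)
        } else if (arch == "attentivefp") {
          add_lin(paste0(pre, "_ctx"), d, d, bias = FALSE)
          add_lin(paste0(pre, "_att"), 2L * d + edge_in, 1L)
          add_gru(paste0(pre, "_gru"), d, d)
        } else if (arch == "pagtn") {
          add_lin(pre, d, d, bias = FALSE)
          p[[paste0(pre, "_asrc")]] <<- init_mat(d, 1L)
          p[[paste0(pre, "_adst")]] <<- init_mat(d, 1L)
          p[[paste0(pre, "_apath")]] <<- init_mat(edge_in + cfg$path_hops, 1L)
        } else if (arch == "graphormer") {
          for (m in c("q", "k", "v", "o")) add_lin(paste0(pre, "_", m), d, d)
          add_lin(paste0(pre, "_ffn1"), d, cfg$ffn_dim)
          add_lin(paste0(pre, "_ffn2"), cfg$ffn_dim, d)
          p[[paste0(pre, "_ln_gamma")]] <<- rep(1, d)
          p[[paste0(pre, "_ln_beta")]] <<- rep(0, d)
        }
      }
    }
    layer_params()
    if (arch == "graphormer") {
      p$degree_embed <- init_mat(4L, d, fan_in = 1) * 0.1
      p$spd_bias <- matrix(0, cfg$max_spd + 1L, cfg$n_heads)
      p$edge_bias <- matrix(0, edge_in, cfg$n_heads)
    }
    ro <- cfg$readout
    ro_dim <- switch(ro, weighted_sum_max = 2L * d, sum_max = 2L * d,
                     attentive = d, max = d)
    if (ro == "weighted_sum_max") add_lin("gate", d, 1L)
    if (ro == "attentive") { add_lin("ro_att", d, 1L); add_lin("ro_ctx", d, d) }
    if (arch == "neuralfp") {
      # GCN-derived fingerprint is frozen; only the 3-layer MLP trains
      frozen <- p[grep("^(proj|layer)", names(p))]
      p <- p[!names(p) %in% names(frozen)]
      add_lin("mlp1", ro_dim, d)
      add_lin("mlp2", d, d)
      if (cfg$norm == "batch") { bn$bn_mlp1 <- d; bn$bn_mlp2 <- d }
      for (nm in c("bn_mlp1", "bn_mlp2")) if (!is.null(bn[[nm]])) {
        p[[paste0(nm, "_gamma")]] <- rep(1, d)
        p[[paste0(nm, "_beta")]] <- rep(0, d)
      }
      rep_dim <- d
    } else {
      add_lin("mlp1", ro_dim, d)
      if (cfg$norm == "batch") {
        bn$bn_mlp1 <- d
        p$bn_mlp1_gamma <- rep(1, d)
        p$bn_mlp1_beta <- rep(0, d)
      }
      rep_dim <- d
    }
  } else if (arch == "fixed_embedding") {
    # pair inputs concatenate the two provider vectors BEFORE the MLP, so
    # the hidden layers see both sides jointly (head input width 2 x dim)
    in_dim <- provider$dimension * if (task$arity == "pair") 2L else 1L
    add_lin("mlp1", in_dim, d)
    add_lin("mlp2", d, d)
    rep_dim <- d
  }

  head_in <- if (task$arity == "pair" && arch != "fixed_embedding")
    2L * rep_dim else rep_dim
  if (task$level == "residue") head_in <- rep_dim
  add_lin("head", head_in, out_dim)
  list(trainable = p, frozen = frozen, bn_dims = bn)
}

#' Save and load model checkpoints
#'
#' A checkpoint is a single-file archive of the model's named parameters
#' with its configuration, task, and normalization state embedded, so a
#' reloaded model predicts identically. Embedding providers are stored by
#' reconstruction recipe only when shipped ones are used; custom providers
#' must be re-attached after loading.
#'
#' @param model A `pb_model`.
#' @param path File path for the checkpoint.
#' @return `save_checkpoint`: `path`, invisibly. `load_checkpoint`: the
#'   restored `pb_model`.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "pb_model"))
  state <- lapply(ls(model$state), function(nm) {
    v <- model$state[[nm]]
    if (is.environment(v)) as.list(v) else v
  })
  names(state) <- ls(model$state)
  saveRDS(list(architecture = model$architecture, task = model$task,
               config = model$config, params = model$params,
               frozen = model$frozen, state = state,
               init_seed = model$init_seed,
               provider_name = model$provider$name), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @param provider An [embedding_provider()] to re-attach (fixed-embedding
#'   checkpoints only).
#' @export
load_checkpoint <- function(path, provider = NULL) {
  ck <- readRDS(path)
  if (ck$architecture == "fixed_embedding" && is.null(provider)) {
    pb_stop("pb_missing_provider",
            "re-attach the embedding provider when loading this checkpoint")
  }
  state <- new.env(parent = emptyenv())
  for (nm in names(ck$state)) {
    v <- ck$state[[nm]]
    if (is.list(v) && !is.null(v$running_mean)) {
      e <- new.env(parent = emptyenv())
      for (f in names(v)) e[[f]] <- v[[f]]
      state[[nm]] <- e
    } else {
      state[[nm]] <- v
    }
  }
  structure(list(architecture = ck$architecture, task = ck$task,
                 config = ck$config, params = ck$params, frozen = ck$frozen,
                 state = state, provider = provider,
                 init_seed = ck$init_seed),
            class = "pb_model")
}
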
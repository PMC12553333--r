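# Task-conditioned losses, seeded mini-batch Adam optimization, prediction.
#
# Loss selection is a pure function of the task: regression uses mean squared
# error; single-protein classification (binary included) uses softmax
# cross-entropy; pair classification uses sigmoid + binary cross-entropy;
# residue tasks use per-token softmax cross-entropy averaged over the true
# (non-pad) length of each sequence, then over the batch. The binary
# single-vs-pair asymmetry (softmax vs sigmoid) mirrors the training flow
# this library implements.

#' Loss specification for a task
#'
#' @param task A [task_spec()].
#' @return A `pb_loss_spec` with `kind` in `mse`, `cross_entropy`,
#'   `binary_cross_entropy`, `residue_cross_entropy`.
#' @export
loss_for_task <- function(task) {
  kind <- if (task$level == "residue") {
    "residue_cross_entropy"
  } else if (task$objective == "regression") {
    "mse"
  } else if (task$arity == "pair") {
    "binary_cross_entropy"   # pair labels are 0/1; sigmoid head
  } else {
    "cross_entropy"          # softmax head, also for the binary case
  }
  structure(list(kind = kind, reduction = "mean"), class = "pb_loss_spec")
}

# labels as plain vectors (or list of vectors for residue tasks)
record_labels <- function(records, task) {
  if (task$level == "residue") lapply(records, function(r) r$residue_labels)
  else vapply(records, function(r) as.numeric(r$label), numeric(1L))
}

# Attach the right loss node for a forward output.
batch_loss <- function(tape, out, task, labels, batch = NULL, max_length = 300L) {
  kind <- loss_for_task(task)$kind
  if (kind == "mse") {
    ad_loss_mse(tape, out, matrix(labels, ncol = 1L))
  } else if (kind == "binary_cross_entropy") {
    ad_loss_bce_logits(tape, out, labels)
  } else if (kind == "cross_entropy") {
    ad_loss_softmax_ce(tape, out, as.integer(labels) + 1L)
  } else {
    # residue: flat (B*L, C) logits; averaged over true length per sequence
    L <- ncol(batch$mask)
    lens <- batch$lengths
    cls <- integer(nrow(batch$mask) * L)
    w <- numeric(length(cls))
    for (i in seq_along(labels)) {
      li <- labels[[i]]
      if (length(li) > max_length) li <- li[seq_len(max_length)]
      rows <- ((i - 1L) * L + 1L):((i - 1L) * L + length(li))
      cls[rows] <- as.integer(li) + 1L
      w[rows] <- 1 / lens[i]
    }
    cls[cls == 0L] <- 1L  # pad rows: weight 0, class index only placates indexing
    ad_loss_softmax_ce(tape, out, cls, weight = w)
  }
}

adam_init <- function(params) {
  st <- new.env(parent = emptyenv())
  st$t <- 0L
  st$m <- lapply(params, function(p) array(0, dim = dim(p) %||% length(p)))
  st$v <- lapply(params, function(p) array(0, dim = dim(p) %||% length(p)))
  st
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(params, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (st$m[[nm]] / bc1) / (sqrt(st$v[[nm]] / bc2) + eps)
    if (weight_decay > 0) {
      params[[nm]] <- params[[nm]] - lr * weight_decay * params[[nm]]
    }
  }
  params
}

#' Train a model on a dataset split
#'
#' Seeded mini-batch Adam training (batch size 32 by default, canonical Adam
#' moments). Runs up to `config$max_epochs` epochs over shuffled mini-batches
#' and returns the final-epoch model together with the full per-epoch
#' history (training loss and, when `eval_valid`, validation metrics), so
#' best-epoch selection remains available post hoc. Identical
#' `(data, config, seed)` reproduce identical results bit for bit.
#'
#' @param model A [build_model()] result.
#' @param split A [make_split()] result.
#' @param config A [train_config()]; `learning_rate = NULL` uses the
#'   architecture default (1e-4 sequence-based, 1e-5 structure-based).
#' @param eval_valid Compute validation metrics each epoch.
#' @param max_length Truncation length for sequence featurization.
#' @param verbose Print one line per epoch.
#' @return List with `model` (trained) and `history` (data.frame).
#' @export
train <- function(model, split, config = train_config(), eval_valid = TRUE,
                  max_length = 300L, verbose = FALSE) {
  stopifnot(inherits(model, "pb_model"), inherits(split, "pb_split"))
  task <- model$task
  lr <- config$learning_rate %||% model$config$learning_rate
  model$config$dropout <- config$dropout
  records <- split$train
  if (length(records) == 0L) pb_stop("pb_empty_batch", "empty training split")
  collate <- prepare_inputs(model, records, max_length)
  if (model$architecture == "fixed_embedding" &&
      is.null(model$state$feat_mean)) {
    all_in <- collate(seq_along(records))
    feats <- if (task$arity == "pair") rbind(all_in$a, all_in$b) else all_in
    model$state$feat_mean <- colMeans(feats)
    model$state$feat_sd <- pmax(apply(feats, 2L, stats::sd), 1e-8)
  }
  labels <- record_labels(records, task)
  st <- adam_init(model$params)
  n <- length(records)
  # sequence batches are length-bucketed (shuffled order, stable length sort,
  # shuffled batch order) so padding tracks the within-batch maximum
  bucket <- model$architecture %in% PB_SEQ_ARCHS
  blens <- if (bucket) {
    vapply(records, function(r) min(nchar(if (task$arity == "pair")
      r$sequence_a else r$sequence), max_length), numeric(1L))
  }
  history <- list()
  with_pb_seed(config$seed, {
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n)
      if (bucket) ord <- ord[order(blens[ord])]
      bidx <- unname(split(ord, ceiling(seq_along(ord) / config$batch_size)))
      bidx <- bidx[sample.int(length(bidx))]
      epoch_loss <- 0
      for (idx in bidx) {
        input <- collate(idx)
        fw <- pb_forward(model, input, training = TRUE)
        bt <- if (model$architecture %in% PB_SEQ_ARCHS && task$level == "residue")
          input else NULL
        loss <- batch_loss(fw$tape, fw$out, task, labels[idx], batch = bt,
                           max_length = max_length)
        if (!is.finite(ad_value(loss))) {
          pb_stop("pb_nonfinite_loss", sprintf(
            "non-finite training loss at epoch %d", epoch))
        }
        ad_backward(fw$tape, loss)
        grads <- lapply(fw$wrapped, function(w) w$grad)
        model$params <- adam_step(model$params, grads, st, lr,
                                  weight_decay = config$weight_decay %||% 0)
        epoch_loss <- epoch_loss + ad_value(loss) * length(idx)
      }
      row <- list(epoch = epoch, train_loss = epoch_loss / n)
      if (eval_valid && length(split$valid) > 0L) {
        vm <- evaluate_model(model, split$valid, max_length = max_length)
        for (nm in names(vm$metrics)) row[[paste0("valid_", nm)]] <- vm$metrics[[nm]]
      }
      history[[epoch]] <- row
      if (verbose) {
        message(sprintf("epoch %3d  loss %.5f", epoch, row$train_loss))
      }
    }
  })
  hist_df <- if (length(history) > 0L) {
    do.call(rbind, lapply(history, function(r) as.data.frame(r)))
  } else {
    data.frame(epoch = integer(0), train_loss = numeric(0))
  }
  list(model = model, history = hist_df)
}

#' Predict on records
#'
#' One row per record (one row per valid residue position for residue
#' tasks), with raw scores and classification probabilities. Deterministic:
#' dropout is disabled and batch-norm uses running statistics.
#'
#' @param model A `pb_model` (trained or freshly built).
#' @param records Record list matching the model's task.
#' @param batch_size Prediction batch size.
#' @param max_length Truncation length for sequence featurization.
#' @return A data.frame prediction table.
#' @export
predict_records <- function(model, records, batch_size = 64L,
                            max_length = 300L) {
  task <- model$task
  collate <- prepare_inputs(model, records, max_length)
  n <- length(records)
  ids <- vapply(records, function(r) r$id, "")
  # process sequence batches in length order (less padding), then restore
  ord <- if (model$architecture %in% PB_SEQ_ARCHS) {
    order(vapply(records, function(r) nchar(if (task$arity == "pair")
      r$sequence_a else r$sequence), numeric(1L)))
  } else seq_len(n)
  outs <- list()
  for (s in seq(1L, n, by = batch_size)) {
    idx <- ord[s:min(s + batch_size - 1L, n)]
    input <- collate(idx)
    fw <- pb_forward(model, input, training = FALSE)
    o <- ad_value(fw$out)
    if (task$level == "residue") {
      batch <- input
      L <- ncol(batch$mask)
      probs <- exp(o - apply(o, 1L, max))
      probs <- probs / rowSums(probs)
      for (j in seq_along(idx)) {
        len <- batch$lengths[j]
        rows <- ((j - 1L) * L + 1L):((j - 1L) * L + len)
        outs[[length(outs) + 1L]] <- data.frame(
          .pos = idx[j], id = ids[idx[j]], position = seq_len(len),
          pred_class = max.col(probs[rows, , drop = FALSE]) - 1L,
          prob = probs[rows, , drop = FALSE])
      }
    } else if (task$objective == "regression") {
      outs[[length(outs) + 1L]] <- data.frame(.pos = idx, id = ids[idx],
                                               pred = o[, 1L])
    } else if (task$arity == "pair" && task$objective == "binary") {
      p <- stats::plogis(o[, 1L])
      outs[[length(outs) + 1L]] <- data.frame(
        .pos = idx, id = ids[idx], score = o[, 1L], prob = p,
        pred_class = as.integer(p >= 0.5))
    } else {
      probs <- exp(o - apply(o, 1L, max))
      probs <- probs / rowSums(probs)
      outs[[length(outs) + 1L]] <- data.frame(
        .pos = idx, id = ids[idx], pred_class = max.col(probs) - 1L,
        prob = probs)
    }
  }
  out <- do.call(rbind, outs)
  out <- out[order(out$.pos), setdiff(names(out), ".pos"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Predict and score in one call
#'
#' @inheritParams predict_records
#' @return List with `predictions` (table) and `metrics` (named list).
#' @export
evaluate_model <- function(model, records, batch_size = 64L,
                           max_length = 300L) {
  preds <- predict_records(model, records, batch_size, max_length)
  truth <- record_labels(records, model$task)
  if (model$task$level == "residue") {
    truth <- lapply(truth, function(l) l[seq_len(min(length(l), max_length))])
  }
  list(predictions = preds,
       metrics = compute_metrics(model$task, preds, truth))
}
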
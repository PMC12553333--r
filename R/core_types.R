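# Task taxonomy and record types shared by every other module.
#
# Five task types are supported: single-protein regression / classification,
# protein-pair regression / classification, and residue-level classification
# (one class per amino-acid position). A TaskSpec drives featurization, the
# model head, the loss, and metric selection downstream.

pb_stop <- function(class, msg, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "protbench_error")))
}

#' Declare a learning task
#'
#' A task specification fixes the problem shape: how many proteins form one
#' sample (`arity`), whether the label applies to the whole sequence or to
#' every residue (`level`), and the label type (`objective`). All downstream
#' choices — featurization, output head, loss, and metrics — are pure
#' functions of this object.
#'
#' @param name Short identifier for the task.
#' @param arity `"single"` (one protein per sample) or `"pair"` (two).
#' @param level `"sequence"` (one label per sample) or `"residue"` (one label
#'   per amino-acid position; single-arity only).
#' @param objective `"regression"`, `"binary"`, or `"multiclass"`.
#' @param num_classes Number of classes; forced to 2 for binary, must be
#'   at least 3 for multiclass, unused for regression.
#' @return An object of class `pb_task_spec`.
#' @examples
#' task_spec("solubility", "single", "sequence", "binary")
#' task_spec("epitope", "single", "residue", "binary")
#' @export
task_spec <- function(name, arity = c("single", "pair"),
                      level = c("sequence", "residue"),
                      objective = c("regression", "binary", "multiclass"),
                      num_classes = NULL) {
  arity <- match.arg(arity)
  level <- match.arg(level)
  objective <- match.arg(objective)
  if (level == "residue" && arity != "single") {
    pb_stop("pb_invalid_task", "residue-level tasks must be single-arity")
  }
  if (objective == "binary") {
    num_classes <- 2L
  } else if (objective == "multiclass") {
    if (is.null(num_classes) || num_classes < 3) {
      pb_stop("pb_invalid_task", "multiclass tasks need num_classes >= 3")
    }
    num_classes <- as.integer(num_classes)
  } else {
    num_classes <- NA_integer_
  }
  structure(list(name = name, arity = arity, level = level,
                 objective = objective, num_classes = num_classes),
            class = "pb_task_spec")
}

#' @export
print.pb_task_spec <- function(x, ...) {
  cat(sprintf("<task '%s'> arity=%s level=%s objective=%s%s\n", x$name,
              x$arity, x$level, x$objective,
              if (!is.na(x$num_classes)) paste0(" classes=", x$num_classes) else ""))
  invisible(x)
}

#' Labeled sequence records
#'
#' Constructors for the three sample shapes: one protein with one label, a
#' protein pair with one label, and one protein with a per-residue label
#' vector. Classification labels are 0-based class indices.
#'
#' @param id Unique record identifier.
#' @param sequence,sequence_a,sequence_b Amino-acid strings.
#' @param label Real value (regression) or 0-based class index.
#' @param residue_labels Integer vector, one 0-based class per residue.
#' @return A record object (`pb_protein_record`, `pb_pair_record`, or
#'   `pb_residue_record`).
#' @export
protein_record <- function(id, sequence, label = NA_real_) {
  structure(list(id = id, sequence = sequence, label = label),
            class = "pb_protein_record")
}

#' @rdname protein_record
#' @export
pair_record <- function(id, sequence_a, sequence_b, label = NA_real_) {
  structure(list(id = id, sequence_a = sequence_a, sequence_b = sequence_b,
                 label = label),
            class = "pb_pair_record")
}

#' @rdname protein_record
#' @export
residue_record <- function(id, sequence, residue_labels) {
  structure(list(id = id, sequence = sequence,
                 residue_labels = as.integer(residue_labels)),
            class = "pb_residue_record")
}

record_sequences <- function(rec) {
  if (inherits(rec, "pb_pair_record")) c(rec$sequence_a, rec$sequence_b)
  else rec$sequence
}

map_record_sequences <- function(rec, f) {
  if (inherits(rec, "pb_pair_record")) {
    rec$sequence_a <- f(rec$sequence_a)
    rec$sequence_b <- f(rec$sequence_b)
  } else {
    rec$sequence <- f(rec$sequence)
  }
  rec
}

#' Validate records against a task specification
#'
#' Checks every record's shape against the task: non-empty sequences,
#' residue-label vectors of matching length, class labels inside
#' `[0, num_classes)`. Characters outside the 21-symbol vocabulary (the 20
#' canonical amino acids plus the unknown symbol `X`) are mapped to `X` with
#' one warning. Validation is idempotent.
#'
#' @param records List of records (see [protein_record()]).
#' @param task A [task_spec()].
#' @return The validated (possibly rewritten) record list.
#' @export
validate_records <- function(records, task) {
  expected <- switch(task$arity, single = if (task$level == "residue")
    "pb_residue_record" else "pb_protein_record", pair = "pb_pair_record")
  n_unknown <- 0L
  out <- lapply(records, function(rec) {
    if (!inherits(rec, expected)) {
      pb_stop("pb_record_type", sprintf(
        "task '%s' expects %s records, got %s", task$name, expected,
        class(rec)[1L]))
    }
    for (s in record_sequences(rec)) {
      if (is.na(s) || !nzchar(s)) {
        pb_stop("pb_empty_sequence",
                sprintf("record '%s' has an empty sequence", rec$id))
      }
    }
    rec <- map_record_sequences(rec, function(s) {
      s <- toupper(s)
      bad <- !strsplit(s, "")[[1L]] %in% AA_SYMBOLS
      if (any(bad)) {
        n_unknown <<- n_unknown + sum(bad)
        ch <- strsplit(s, "")[[1L]]
        ch[bad] <- "X"
        s <- paste(ch, collapse = "")
      }
      s
    })
    if (inherits(rec, "pb_residue_record")) {
      if (length(rec$residue_labels) != nchar(rec$sequence)) {
        pb_stop("pb_length_mismatch", sprintf(
          "record '%s': %d residue labels for a length-%d sequence",
          rec$id, length(rec$residue_labels), nchar(rec$sequence)))
      }
    }
    if (task$objective != "regression") {
      labs <- if (inherits(rec, "pb_residue_record")) rec$residue_labels else rec$label
      if (any(!is.na(labs) & (labs < 0 | labs >= task$num_classes | labs != floor(labs)))) {
        pb_stop("pb_label_out_of_range", sprintf(
          "record '%s': labels must be integers in [0, %d)", rec$id,
          task$num_classes))
      }
    }
    rec
  })
  if (n_unknown > 0L) {
    warning(sprintf("%d non-canonical residue(s) mapped to the unknown symbol 'X'",
                    n_unknown), call. = FALSE)
  }
  out
}

#' Split records into train / validation / test parts
#'
#' Deterministic seeded partition. Part sizes are the rounded ratio shares
#' (largest-remainder rounding so sizes always sum to the input size); every
#' record lands in exactly one part.
#'
#' @param records List of records.
#' @param ratios Length-3 positive vector summing to 1 (train, valid, test).
#' @param seed Integer seed controlling the permutation.
#' @return A `pb_split`: list with `train`, `valid`, `test`, and `seed`.
#' @export
make_split <- function(records, ratios = c(0.8, 0.1, 0.1), seed = 1L) {
  stopifnot(length(ratios) == 3L, all(ratios > 0))
  if (abs(sum(ratios) - 1) > 1e-8) {
    pb_stop("pb_invalid_ratios", "split ratios must sum to 1")
  }
  n <- length(records)
  share <- n * ratios
  sizes <- floor(share)
  rem <- n - sum(sizes)
  if (rem > 0) {
    extra <- order(share - sizes, decreasing = TRUE)[seq_len(rem)]
    sizes[extra] <- sizes[extra] + 1L
  }
  if (any(sizes == 0L)) {
    pb_stop("pb_too_few_records", sprintf(
      "%d records cannot fill all three split parts at ratios %s", n,
      paste(ratios, collapse = "/")))
  }
  perm <- with_pb_seed(seed, sample.int(n))
  idx <- split(perm, rep.int(1:3, sizes))
  structure(list(train = records[idx[[1L]]], valid = records[idx[[2L]]],
                 test = records[idx[[3L]]], seed = as.integer(seed)),
            class = "pb_split")
}

# Run expr under a temporary RNG state seeded with `seed`.
with_pb_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Training hyperparameters
#'
#' Defaults follow the library-wide baseline: batch size 32, up to 100
#' epochs, dropout 0.1, and a learning rate of 1e-4 for sequence-based
#' architectures (1e-5 is the structure-based default, applied by
#' [build_model()] consumers via `lr = NULL`).
#'
#' @param learning_rate Adam step size; `NULL` picks the architecture default.
#' @param batch_size Mini-batch size.
#' @param max_epochs Maximum number of passes over the training split.
#' @param seed Integer seed for shuffling, dropout, and initialization.
#' @param dropout Dropout probability in `[0, 1)`.
#' @param weight_decay Decoupled weight-decay coefficient (0 disables).
#' @return A `pb_train_config` list.
#' @export
train_config <- function(learning_rate = NULL, batch_size = 32L,
                         max_epochs = 100L, seed = 1L, dropout = 0.1,
                         weight_decay = 0) {
  stopifnot(is.null(learning_rate) || learning_rate > 0, batch_size >= 1,
            max_epochs >= 0, dropout >= 0, dropout < 1, weight_decay >= 0)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 seed = as.integer(seed), dropout = dropout,
                 weight_decay = weight_decay),
            class = "pb_train_config")
}
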
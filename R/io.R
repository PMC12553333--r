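# File formats, prompt templates, and the benchmark orchestrator.
#
# Formats: FASTA for raw sequences, CSV task tables with header
# `id,sequence[,sequence_b],label` (residue labels are a digit string of the
# same length as the sequence), CSV histories/leaderboards, JSON metric
# reports and provenance sidecars.

#' Read a FASTA file into unlabeled protein records
#'
#' The header up to the first whitespace becomes the record id; sequences
#' are uppercased.
#'
#' @param path FASTA file path.
#' @return List of [protein_record()]s (labels `NA`).
#' @export
read_fasta <- function(path) {
  txt <- readLines(path, warn = FALSE)
  if (!any(startsWith(txt, ">"))) {
    pb_stop("pb_malformed_fasta", sprintf("'%s' contains no FASTA headers", path))
  }
  set <- tryCatch(Biostrings::readAAStringSet(path),
                  error = function(e) pb_stop("pb_malformed_fasta", conditionMessage(e)))
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, "", 1L)
  mapply(function(id, s) protein_record(id, toupper(s)),
         ids, as.character(set), SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Read and write CSV task tables
#'
#' Task tables have header `id,sequence,label` (single tasks),
#' `id,sequence,sequence_b,label` (pair tasks); residue tasks encode the
#' per-position labels as a digit string of the same length as `sequence`.
#' Reading validates through [validate_records()].
#'
#' @param path CSV path.
#' @param task A [task_spec()].
#' @param records Record list (for writing).
#' @return `read_task_table`: validated record list. `write_task_table`:
#'   the path, invisibly.
#' @export
read_task_table <- function(path, task) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- if (task$arity == "pair") c("id", "sequence", "sequence_b", "label")
          else c("id", "sequence", "label")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    pb_stop("pb_missing_column", sprintf("task table lacks column(s): %s",
                                         paste(miss, collapse = ", ")))
  }
  recs <- lapply(seq_len(nrow(df)), function(i) {
    if (task$arity == "pair") {
      pair_record(df$id[i], df$sequence[i], df$sequence_b[i],
                  as.numeric(df$label[i]))
    } else if (task$level == "residue") {
      lab <- as.integer(strsplit(df$label[i], "")[[1L]])
      residue_record(df$id[i], df$sequence[i], lab)
    } else {
      protein_record(df$id[i], df$sequence[i], as.numeric(df$label[i]))
    }
  })
  validate_records(recs, task)
}

#' @rdname read_task_table
#' @export
write_task_table <- function(records, path, task) {
  df <- if (task$arity == "pair") {
    data.frame(id = vapply(records, `[[`, "", "id"),
               sequence = vapply(records, `[[`, "", "sequence_a"),
               sequence_b = vapply(records, `[[`, "", "sequence_b"),
               label = vapply(records, function(r) as.character(r$label), ""))
  } else if (task$level == "residue") {
    data.frame(id = vapply(records, `[[`, "", "id"),
               sequence = vapply(records, `[[`, "", "sequence"),
               label = vapply(records, function(r)
                 paste(r$residue_labels, collapse = ""), ""))
  } else {
    data.frame(id = vapply(records, `[[`, "", "id"),
               sequence = vapply(records, `[[`, "", "sequence"),
               label = vapply(records, function(r) as.character(r$label), ""))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## ---- LLM prompt formatting (string construction only) ----

PB_PROMPT_REGISTRY <- list(
  Fluorescence = c("Fluorescence intensity", "You should return a floating-point number."),
  Beta = c("Increased activity", "You should return a floating-point number."),
  Stability = c("Protein stability", "You should return a floating-point number."),
  Solubility = c("Protein solubility", "You should return an integer (0 or 1) where 0 is not soluble and 1 is soluble."),
  Subcellular = c("Location", "You should choose an integer within the range [0, 9] to indicate the protein's location."),
  Subcellular_Binary = c("Location", "You should return an integer (0 or 1) where 0 is membrane-bound and 1 is soluble."),
  Tap = c("Developability", "You should return a floating-point number."),
  SAbDab_Chen = c("Developability", "You should return a floating-point number."),
  CRISPR = c("Repair outcome", "You should return a floating-point number."),
  `PPI-Affinity` = c("Activity of PPI", "You should return a floating-point number."),
  `Yeast-PPI` = c("Activity of PPI", "You should return an integer (0 or 1) where 0 is weak and 1 is strong."),
  `Human-PPI` = c("Activity of PPI", "You should return an integer (0 or 1) where 0 is weak and 1 is strong."),
  Fold = c("Global structural topology of a protein on the fold level", "You should return an integer within the range [0, 1194]."),
  Secondary = c("Local structures of protein residues in their natural state", "You should return an integer within the range [0, 2].")
)

#' Render an LLM prompt for a registered dataset
#'
#' Builds the instruction-following prompt string for a dataset's property
#' prediction question. `"plain"` wraps the sequence in protein delimiter
#' tokens inside a single question; `"chat_delimited"` renders the
#' chat-format template (system instruction plus `im_start`/`im_end`
#' delimited user turn). String construction only — nothing is sent to any
#' model.
#'
#' @param dataset_name Registered dataset name (see names of the registry).
#' @param sequence Protein sequence to embed (appears exactly once).
#' @param style `"plain"` or `"chat_delimited"`.
#' @return The prompt string.
#' @export
format_llm_prompt <- function(dataset_name, sequence,
                              style = c("plain", "chat_delimited")) {
  style <- match.arg(style)
  entry <- PB_PROMPT_REGISTRY[[dataset_name]]
  if (is.null(entry)) {
    pb_stop("pb_unknown_dataset", sprintf(
      "no prompt registration for dataset '%s'", dataset_name))
  }
  property <- entry[1L]; instruction <- entry[2L]
  question <- sprintf(
    "What is the %s of the given protein sequence <PROTEIN> %s </PROTEIN>? %s",
    property, sequence, instruction)
  if (style == "plain") return(question)
  paste0(
    "System Instruction: You are an AI assistant specializing in protein ",
    "property prediction. Follow the given instruction format.\n",
    "<|im_start|>user\n",
    sprintf("What is the %s of the given protein sequence %s? %s\n",
            property, sequence, instruction),
    "<|im_end|>\n<|im_start|>assistant\n")
}

## ---- benchmark orchestration ----

#' Configure a benchmark run
#'
#' @param task A [task_spec()].
#' @param records Record list, or `NULL` to generate from `generator`.
#' @param generator A [generator_spec()] (used when `records` is `NULL`).
#' @param architectures Character vector of architecture names.
#' @param seeds Integer vector of distinct replicate seeds (model init,
#'   shuffling, dropout). The split itself is fixed by `split_seed`.
#' @param train A [train_config()] template (its seed is overridden per
#'   replicate).
#' @param split_seed Seed of the shared train/valid/test split.
#' @param out_dir Output directory for CSV/JSON artifacts.
#' @param provider Optional [embedding_provider()] for fixed_embedding runs.
#' @return A `pb_run_config`.
#' @export
run_config <- function(task, records = NULL, generator = NULL,
                       architectures = c("cnn"), seeds = c(1L, 2L, 3L),
                       train = train_config(), split_seed = 1L,
                       out_dir = tempfile("protbench_run_"), provider = NULL) {
  if (anyDuplicated(seeds)) pb_stop("pb_invalid_spec", "replicate seeds must be distinct")
  if (is.null(records) && is.null(generator)) {
    pb_stop("pb_invalid_spec", "either records or a generator must be given")
  }
  structure(list(task = task, records = records, generator = generator,
                 architectures = architectures, seeds = as.integer(seeds),
                 train = train, split_seed = as.integer(split_seed),
                 out_dir = out_dir, provider = provider),
            class = "pb_run_config")
}

run_config_hash <- function(rc) {
  strip <- rc[c("task", "architectures", "seeds", "train", "split_seed")]
  strip$generator <- if (!is.null(rc$generator)) {
    g <- unclass(rc$generator); g$task <- unclass(g$task); g
  }
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(strip, f, auto_unbox = TRUE, force = TRUE, digits = NA)
  unname(tools::md5sum(f))
}

#' Run the full multi-seed benchmark protocol
#'
#' For every (architecture, replicate seed): build, train, and evaluate on
#' the shared held-out test split; then aggregate mean and standard
#' deviation per metric into a leaderboard and compare every architecture
#' pair on the task's headline metric with a two-sample t test. Artifacts
#' (results, leaderboard, comparisons, per-run histories, provenance
#' sidecar) are written as CSV/JSON under `out_dir`; a failing architecture
#' is logged and skipped without losing the others' rows. Fully
#' deterministic given the seed list.
#'
#' @param rc A [run_config()].
#' @param alpha Significance level for pairwise comparisons.
#' @param verbose Print progress lines.
#' @return List with `results`, `leaderboard`, `comparisons`, `failures`,
#'   and `out_dir`, invisibly.
#' @export
run_benchmark <- function(rc, alpha = 0.05, verbose = FALSE) {
  stopifnot(inherits(rc, "pb_run_config"))
  records <- rc$records %||% generate_records(rc$generator)
  split <- make_split(records, seed = rc$split_seed)
  dir.create(rc$out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- run_config_hash(rc)
  primary <- switch(rc$task$objective, regression = "spearman",
                    binary = "roc_auc", multiclass = "macro_f1")
  rows <- list(); failures <- list()
  for (arch in rc$architectures) {
    for (s in rc$seeds) {
      tag <- sprintf("%s_seed%d", arch, s)
      res <- tryCatch({
        cfg <- rc$train
        cfg$seed <- s
        model <- build_model(arch, rc$task, seed = s, provider = rc$provider)
        fit <- train(model, split, cfg, eval_valid = FALSE)
        ev <- evaluate_model(fit$model, split$test)
        utils::write.csv(cbind(fit$history, config_hash = hash, seed = s),
                         file.path(rc$out_dir, paste0("history_", tag, ".csv")),
                         row.names = FALSE)
        c(list(model = arch, task = rc$task$name, seed = s), ev$metrics)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failures[[tag]] <- conditionMessage(res)
        if (verbose) message(sprintf("[%s] FAILED: %s", tag, conditionMessage(res)))
      } else {
        rows[[tag]] <- as.data.frame(res)
        if (verbose) {
          message(sprintf("[%s] %s = %.4f", tag, primary, res[[primary]]))
        }
      }
    }
  }
  results <- if (length(rows)) do.call(rbind, rows) else
    data.frame(model = character(0), task = character(0), seed = integer(0))
  rownames(results) <- NULL
  lb <- if (nrow(results)) cbind(leaderboard(results), config_hash = hash)
        else results
  comparisons <- NULL
  archs_ok <- unique(results$model)
  if (length(archs_ok) >= 2L) {
    pairs <- utils::combn(archs_ok, 2L)
    comparisons <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
      a <- pairs[1L, j]; b <- pairs[2L, j]
      cmp <- compare_methods(results[[primary]][results$model == a],
                             results[[primary]][results$model == b],
                             alpha = alpha)
      data.frame(model_a = a, model_b = b, metric = primary,
                 mean_a = cmp$mean_a, mean_b = cmp$mean_b, t = cmp$t,
                 p_value = cmp$p_value, verdict = cmp$verdict,
                 config_hash = hash)
    }))
  }
  utils::write.csv(cbind(results, config_hash = hash),
                   file.path(rc$out_dir, "results.csv"), row.names = FALSE)
  if (nrow(results)) {
    utils::write.csv(lb, file.path(rc$out_dir, "leaderboard.csv"),
                     row.names = FALSE)
  }
  if (!is.null(comparisons)) {
    utils::write.csv(comparisons, file.path(rc$out_dir, "comparisons.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(
    list(config_hash = hash, seeds = rc$seeds, split_seed = rc$split_seed,
         architectures = rc$architectures, task = unclass(rc$task),
         failures = failures),
    file.path(rc$out_dir, "run_meta.json"), auto_unbox = TRUE, force = TRUE)
  invisible(list(results = results, leaderboard = lb,
                 comparisons = comparisons, failures = failures,
                 out_dir = rc$out_dir))
}
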
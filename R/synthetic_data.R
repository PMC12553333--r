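# Seeded planted-motif generators emulating the five task types, so the
# whole pipeline (featurization -> model -> training -> metrics) is
# exercisable without any external dataset.
#
# Signal is always a short amino-acid motif inserted into an otherwise
# uniform background: motif *counts* drive regression labels, motif
# *identity* drives classification, motif *positions* drive residue labels,
# and motif *complementarity* / shared counts drive pair tasks. Every
# generator is a pure function of (spec, seed).

pb_default_motifs <- function(task) {
  if (task$level == "residue") return(stats::setNames(1, "WCMW"))
  if (task$arity == "pair") {
    if (task$objective == "regression") {
      # shared residue-content score (complementary composition); the score
      # must be expressible from generic per-sequence features, which keeps
      # the non-neural count oracle an attainable ceiling for trained heads
      return(stats::setNames(c(1, 1.5, 2, 2.5), c("W", "C", "H", "M")))
    }
    return(stats::setNames(c(1, 1), c("CHWK", "KWHC")))  # complementary pair
  }
  if (task$objective == "regression") return(stats::setNames(1, "HWCK"))
  k <- task$num_classes
  motifs <- with_pb_seed(971L + k, vapply(seq_len(k), function(i)
    paste(sample(AA_CANONICAL, 5L, replace = TRUE), collapse = ""), ""))
  stats::setNames(rep(1, k), motifs)
}

#' Specify a synthetic planted-motif dataset
#'
#' @param task A [task_spec()] (drives which generator runs).
#' @param n_samples Number of records.
#' @param length_range Min/max sequence length (residues). Defaults to
#'   50-200 so truncation at 300 never interferes outside dedicated tests.
#' @param motifs Named numeric vector: names are motif strings, values their
#'   effect weights. `NULL` uses task-appropriate defaults. For pair
#'   classification the first two motifs form the complementary pair; for
#'   pair regression the motifs are the shared k-mer dictionary.
#' @param noise_sd Gaussian label noise (regression tasks).
#' @param flip_prob Label flip probability in `[0, 0.5)` (classification).
#' @param motifs_per_seq Inserted motif copies per sequence (residue tasks).
#' @param insert_rate Poisson mean of inserted copies per motif (count-driven
#'   tasks).
#' @param seed Integer seed; generation is a pure function of (spec, seed).
#' @return A `pb_generator_spec`.
#' @export
generator_spec <- function(task, n_samples, length_range = c(50L, 200L),
                           motifs = NULL, noise_sd = 0.1, flip_prob = 0.05,
                           motifs_per_seq = 3L, insert_rate = 1.5, seed = 1L) {
  stopifnot(inherits(task, "pb_task_spec"), n_samples >= 1,
            length(length_range) == 2L, length_range[1L] <= length_range[2L])
  if (is.null(motifs)) motifs <- pb_default_motifs(task)
  if (length(motifs) == 0L || is.null(names(motifs)) || any(!nzchar(names(motifs)))) {
    pb_stop("pb_invalid_spec", "motifs must be a named (motif -> weight) vector")
  }
  if (flip_prob < 0 || flip_prob >= 0.5) {
    pb_stop("pb_invalid_spec", "flip_prob must lie in [0, 0.5)")
  }
  if (noise_sd < 0) pb_stop("pb_invalid_spec", "noise_sd must be >= 0")
  if (length_range[1L] < max(nchar(names(motifs)))) {
    pb_stop("pb_invalid_spec", "minimum length is shorter than the longest motif")
  }
  if (task$objective == "multiclass" && task$arity == "single" &&
      task$level == "sequence" && length(motifs) < task$num_classes) {
    pb_stop("pb_invalid_spec", "need one motif per class")
  }
  structure(list(task = task, n_samples = as.integer(n_samples),
                 length_range = as.integer(length_range), motifs = motifs,
                 noise_sd = noise_sd, flip_prob = flip_prob,
                 motifs_per_seq = as.integer(motifs_per_seq),
                 insert_rate = insert_rate, seed = as.integer(seed)),
            class = "pb_generator_spec")
}

rand_background <- function(len, forbid = character(0)) {
  repeat {
    s <- paste(sample(AA_CANONICAL, len, replace = TRUE), collapse = "")
    if (length(forbid) == 0L || !any(vapply(forbid, grepl, TRUE, x = s, fixed = TRUE)))
      return(s)
  }
}

count_motif <- function(seq, motif) {  # overlapping occurrences
  m <- gregexpr(paste0("(?=", motif, ")"), seq, perl = TRUE)[[1L]]
  if (m[1L] == -1L) 0L else length(m)
}

# non-overlapping insertion positions for `k` copies of an `mlen`-long motif
place_positions <- function(len, k, mlen, max_tries = 200L) {
  taken <- integer(0)
  for (i in seq_len(k)) {
    for (try in seq_len(max_tries)) {
      p <- sample.int(len - mlen + 1L, 1L)
      if (!any(abs(p - taken) < mlen)) { taken <- c(taken, p); break }
    }
  }
  taken
}

insert_at <- function(seq, motif, positions) {
  for (p in positions) substr(seq, p, p + nchar(motif) - 1L) <- motif
  seq
}

#' Generate synthetic records
#'
#' Dispatches on the spec's task to the matching planted-motif generator:
#' single regression (label = weighted motif count + Gaussian noise), single
#' classification (class-specific motifs, balanced to one record, labels
#' flipped with `flip_prob`), pair regression (weighted shared-motif-count
#' score: sum over the dictionary of weight times the smaller of the two
#' counts), pair classification (complementary motif pair, symmetric in the
#' two sequences), or residue labeling (label 1 exactly at inserted motif
#' positions, then position-wise flips).
#'
#' @param spec A [generator_spec()].
#' @return List of validated records.
#' @export
generate_records <- function(spec) {
  stopifnot(inherits(spec, "pb_generator_spec"))
  task <- spec$task
  recs <- with_pb_seed(spec$seed, {
    if (task$level == "residue") gen_residue_(spec)
    else if (task$arity == "pair") {
      if (task$objective == "regression") gen_pair_regression_(spec)
      else gen_pair_classification_(spec)
    } else if (task$objective == "regression") gen_single_regression_(spec)
    else gen_single_classification_(spec)
  })
  suppressWarnings(validate_records(recs, task))
}

gen_single_regression_ <- function(spec) {
  motifs <- names(spec$motifs)
  lapply(seq_len(spec$n_samples), function(i) {
    len <- sample(spec$length_range[1L]:spec$length_range[2L], 1L)
    s <- rand_background(len)
    for (m in motifs) {
      k <- stats::rpois(1L, spec$insert_rate)
      if (k > 0L) s <- insert_at(s, m, place_positions(len, k, nchar(m)))
    }
    y <- sum(vapply(motifs, function(m) spec$motifs[[m]] * count_motif(s, m),
                    numeric(1L)))
    if (spec$noise_sd > 0) y <- y + stats::rnorm(1L, 0, spec$noise_sd)
    protein_record(sprintf("s%05d", i), s, y)
  })
}

gen_single_classification_ <- function(spec) {
  C <- spec$task$num_classes
  motifs <- names(spec$motifs)[seq_len(C)]
  classes <- rep_len(0:(C - 1L), spec$n_samples)  # balanced to +/- 1
  lapply(seq_len(spec$n_samples), function(i) {
    len <- sample(spec$length_range[1L]:spec$length_range[2L], 1L)
    s <- rand_background(len, forbid = motifs)
    cls <- classes[i]
    s <- insert_at(s, motifs[cls + 1L],
                   place_positions(len, 1L, nchar(motifs[cls + 1L])))
    lab <- cls
    if (spec$flip_prob > 0 && stats::runif(1L) < spec$flip_prob) {
      lab <- sample(setdiff(0:(C - 1L), cls), 1L)
    }
    protein_record(sprintf("s%05d", i), s, lab)
  })
}

gen_pair_regression_ <- function(spec) {
  motifs <- names(spec$motifs)
  one_side <- function(len) {
    s <- rand_background(len)
    for (m in motifs) {
      k <- stats::rpois(1L, spec$insert_rate)
      if (k > 0L) s <- insert_at(s, m, place_positions(len, k, nchar(m)))
    }
    s
  }
  lapply(seq_len(spec$n_samples), function(i) {
    la <- sample(spec$length_range[1L]:spec$length_range[2L], 1L)
    lb <- sample(spec$length_range[1L]:spec$length_range[2L], 1L)
    a <- one_side(la); b <- one_side(lb)
    y <- sum(vapply(motifs, function(m)
      spec$motifs[[m]] * min(count_motif(a, m), count_motif(b, m)),
      numeric(1L)))
    if (spec$noise_sd > 0) y <- y + stats::rnorm(1L, 0, spec$noise_sd)
    pair_record(sprintf("p%05d", i), a, b, y)
  })
}

gen_pair_classification_ <- function(spec) {
  if (length(spec$motifs) < 2L) {
    pb_stop("pb_invalid_spec", "pair classification needs a motif pair")
  }
  m1 <- names(spec$motifs)[1L]; m2 <- names(spec$motifs)[2L]
  classes <- rep_len(0:1, spec$n_samples)
  lapply(seq_len(spec$n_samples), function(i) {
    la <- sample(spec$length_range[1L]:spec$length_range[2L], 1L)
    lb <- sample(spec$length_range[1L]:spec$length_range[2L], 1L)
    a <- rand_background(la, forbid = c(m1, m2))
    b <- rand_background(lb, forbid = c(m1, m2))
    cls <- classes[i]
    if (cls == 1L) {  # complementary pair present, random side assignment
      if (stats::runif(1L) < 0.5) {
        a <- insert_at(a, m1, place_positions(la, 1L, nchar(m1)))
        b <- insert_at(b, m2, place_positions(lb, 1L, nchar(m2)))
      } else {
        a <- insert_at(a, m2, place_positions(la, 1L, nchar(m2)))
        b <- insert_at(b, m1, place_positions(lb, 1L, nchar(m1)))
      }
    } else {          # at most one half of the pair
      u <- stats::runif(1L)
      if (u < 1 / 3) a <- insert_at(a, m1, place_positions(la, 1L, nchar(m1)))
      else if (u < 2 / 3) b <- insert_at(b, m2, place_positions(lb, 1L, nchar(m2)))
    }
    lab <- cls
    if (spec$flip_prob > 0 && stats::runif(1L) < spec$flip_prob) lab <- 1L - lab
    pair_record(sprintf("p%05d", i), a, b, lab)
  })
}

gen_residue_ <- function(spec) {
  motif <- names(spec$motifs)[1L]
  mlen <- nchar(motif)
  lapply(seq_len(spec$n_samples), function(i) {
    len <- sample(spec$length_range[1L]:spec$length_range[2L], 1L)
    s <- rand_background(len, forbid = motif)
    pos <- place_positions(len, spec$motifs_per_seq, mlen)
    s <- insert_at(s, motif, pos)
    lab <- integer(len)
    for (p in pos) lab[p:(p + mlen - 1L)] <- 1L
    if (spec$flip_prob > 0) {
      fl <- stats::runif(len) < spec$flip_prob
      lab[fl] <- 1L - lab[fl]
    }
    residue_record(sprintf("r%05d", i), s, lab)
  })
}
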
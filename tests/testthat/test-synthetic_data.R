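count_oracle <- function(s, m) {
  # dumb scan, independent of the generator's counter
  n <- 0L
  for (i in seq_len(nchar(s) - nchar(m) + 1L)) {
    if (substr(s, i, i + nchar(m) - 1L) == m) n <- n + 1L
  }
  n
}

test_that("generators are pure functions of (spec, seed)", {
  task <- task_spec("t", "single", "sequence", "regression")
  g <- generator_spec(task, 20, seed = 5)
  expect_identical(generate_records(g), generate_records(g))
  g2 <- generator_spec(task, 20, seed = 6)
  expect_false(identical(generate_records(g), generate_records(g2)))
})

test_that("noise-free regression labels equal the weighted motif count", {
  task <- task_spec("t", "single", "sequence", "regression")
  g <- generator_spec(task, 40, motifs = c(HWCK = 1), noise_sd = 0, seed = 3)
  recs <- generate_records(g)
  for (r in recs) {
    expect_identical(r$label, as.numeric(count_oracle(r$sequence, "HWCK")))
  }
  # weighted, two motifs
  g2 <- generator_spec(task, 25, motifs = c(HWCK = 2, MMW = 0.5),
                       noise_sd = 0, seed = 4)
  for (r in generate_records(g2)) {
    expect_equal(r$label, 2 * count_oracle(r$sequence, "HWCK") +
                   0.5 * count_oracle(r$sequence, "MMW"))
  }
})

test_that("count regression on true counts recovers the planted weight", {
  task <- task_spec("t", "single", "sequence", "regression")
  g <- generator_spec(task, 3000, motifs = c(HWCK = 1), noise_sd = 0.1,
                      seed = 11)
  recs <- generate_records(g)
  x <- vapply(recs, function(r) count_oracle(r$sequence, "HWCK"), integer(1L))
  y <- vapply(recs, `[[`, numeric(1L), "label")
  w_hat <- coef(lm(y ~ x))[["x"]]  # closed-form least squares oracle
  expect_lt(abs(w_hat - 1), 0.02)
})

test_that("classification is balanced and separable by exact motif scan", {
  task <- task_spec("t", "single", "sequence", "binary")
  g <- generator_spec(task, 101, motifs = c(CWHKC = 1, MYHMW = 1),
                      flip_prob = 0, seed = 7)
  recs <- generate_records(g)
  labs <- vapply(recs, `[[`, numeric(1L), "label")
  expect_lte(abs(sum(labs == 0) - sum(labs == 1)), 1)  # balanced to +/- 1
  scan <- vapply(recs, function(r)
    as.numeric(grepl("MYHMW", r$sequence, fixed = TRUE)), numeric(1L))
  expect_identical(scan, labs)  # accuracy 1.0 at flip 0
  # and no record carries the other class's motif
  cross <- vapply(recs, function(r)
    grepl("CWHKC", r$sequence, fixed = TRUE) &&
      grepl("MYHMW", r$sequence, fixed = TRUE), logical(1L))
  expect_false(any(cross))
})

test_that("label flips hit the requested fraction in expectation", {
  task <- task_spec("t", "single", "sequence", "binary")
  hits <- vapply(1:20, function(s) {
    recs <- generate_records(generator_spec(
      task, 200, motifs = c(CWHKC = 1, MYHMW = 1), flip_prob = 0.1, seed = s))
    scan <- vapply(recs, function(r)
      as.numeric(grepl("MYHMW", r$sequence, fixed = TRUE)), numeric(1L))
    labs <- vapply(recs, `[[`, numeric(1L), "label")
    mean(scan != labs)
  }, numeric(1L))
  expect_lt(abs(mean(hits) - 0.1), 0.02)  # binomial CI at n = 4000
})

test_that("pair regression labels equal the shared-motif-count score", {
  task <- task_spec("t", "pair", "sequence", "regression")
  g <- generator_spec(task, 30, noise_sd = 0, seed = 8)
  recs <- generate_records(g)
  w <- g$motifs
  for (r in recs) {
    sc <- sum(vapply(names(w), function(m)
      w[[m]] * min(count_oracle(r$sequence_a, m),
                   count_oracle(r$sequence_b, m)), numeric(1L)))
    expect_equal(r$label, sc)
  }
  # the defining score is symmetric in the two sequences
  for (r in recs[1:5]) {
    sc_sw <- sum(vapply(names(w), function(m)
      w[[m]] * min(count_oracle(r$sequence_b, m),
                   count_oracle(r$sequence_a, m)), numeric(1L)))
    expect_equal(r$label, sc_sw)
  }
})

test_that("pair classification follows the complementary-motif rule", {
  task <- task_spec("t", "pair", "sequence", "binary")
  g <- generator_spec(task, 60, flip_prob = 0, seed = 9)
  recs <- generate_records(g)
  m1 <- names(g$motifs)[1L]; m2 <- names(g$motifs)[2L]
  rule <- vapply(recs, function(r) {
    a <- r$sequence_a; b <- r$sequence_b
    as.numeric((grepl(m1, a, fixed = TRUE) && grepl(m2, b, fixed = TRUE)) ||
                 (grepl(m2, a, fixed = TRUE) && grepl(m1, b, fixed = TRUE)))
  }, numeric(1L))
  labs <- vapply(recs, `[[`, numeric(1L), "label")
  expect_identical(rule, labs)  # motif-pair rule reaches accuracy 1.0
})

test_that("residue labels mark exactly the inserted motif positions", {
  task <- task_spec("t", "single", "residue", "binary")
  g <- generator_spec(task, 30, motifs = c(WCMW = 1), flip_prob = 0,
                      motifs_per_seq = 2L, seed = 10)
  recs <- generate_records(g)
  for (r in recs) {
    expect_identical(length(r$residue_labels), nchar(r$sequence))
    lab <- r$residue_labels
    # every labeled run is the motif; every motif occurrence is labeled
    runs <- rle(lab)
    starts <- cumsum(c(1L, runs$lengths))[seq_along(runs$values)]
    for (k in which(runs$values == 1L)) {
      expect_identical(runs$lengths[k] %% 4L, 0L)
      expect_identical(substr(r$sequence, starts[k], starts[k] + 3L), "WCMW")
    }
    hits <- gregexpr("(?=WCMW)", r$sequence, perl = TRUE)[[1L]]
    for (p in hits[hits > 0]) {
      expect_identical(lab[p:(p + 3L)], rep(1L, 4L))
    }
  }
})

test_that("residue positive prevalence matches its expectation over seeds", {
  task <- task_spec("t", "single", "residue", "binary")
  prev <- vapply(1:20, function(s) {
    recs <- generate_records(generator_spec(
      task, 40, motifs = c(WCMW = 1), flip_prob = 0, motifs_per_seq = 3L,
      length_range = c(50L, 200L), seed = s))
    labs <- unlist(lapply(recs, `[[`, "residue_labels"))
    mean(labs)
  }, numeric(1L))
  expected <- 4 * 3 / 125  # motif_len * motifs_per_seq / mean_length
  expect_lt(abs(mean(prev) - expected), 0.01)
})

test_that("invalid generator specs are rejected", {
  task <- task_spec("t", "single", "sequence", "regression")
  expect_error(generator_spec(task, 10, motifs = c(1)),
               class = "pb_invalid_spec")
  expect_error(generator_spec(task, 10, flip_prob = 0.6),
               class = "pb_invalid_spec")
  expect_error(generator_spec(task, 10, motifs = c(WWWW = 1),
                              length_range = c(2L, 9L)),
               class = "pb_invalid_spec")
  mt <- task_spec("t", "single", "sequence", "multiclass", 4)
  expect_error(generator_spec(mt, 10, motifs = c(AAA = 1, CCC = 1)),
               class = "pb_invalid_spec")
})
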
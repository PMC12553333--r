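test_that("loss kind is a pure function of the task", {
  expect_identical(loss_for_task(task_spec("a", "single", "sequence",
                                           "regression"))$kind, "mse")
  expect_identical(loss_for_task(task_spec("a", "pair", "sequence",
                                           "regression"))$kind, "mse")
  expect_identical(loss_for_task(task_spec("a", "single", "sequence",
                                           "binary"))$kind, "cross_entropy")
  expect_identical(loss_for_task(task_spec("a", "single", "sequence",
                                           "multiclass", 5))$kind,
                   "cross_entropy")
  expect_identical(loss_for_task(task_spec("a", "pair", "sequence",
                                           "binary"))$kind,
                   "binary_cross_entropy")
  expect_identical(loss_for_task(task_spec("a", "single", "residue",
                                           "binary"))$kind,
                   "residue_cross_entropy")
})

test_that("losses reproduce their closed forms", {
  tape <- pbns$ad_tape()
  # mse(y, y) = 0 and non-negativity
  p <- pbns$ad_leaf(tape, matrix(c(1, 2, 3), ncol = 1))
  expect_equal(pbns$ad_value(pbns$ad_loss_mse(tape, p, matrix(c(1, 2, 3)))), 0)
  expect_gt(pbns$ad_value(pbns$ad_loss_mse(tape, p, matrix(c(1, 2, 4)))), 0)
  # BCE at p = 0.5 (logit 0), y = 1 -> ln 2
  z <- pbns$ad_leaf(tape, matrix(0, 1, 1))
  expect_equal(pbns$ad_value(pbns$ad_loss_bce_logits(tape, z, 1)), log(2),
               tolerance = 1e-12)
  # uniform 3-class softmax -> CE = ln 3 per token
  lg <- pbns$ad_leaf(tape, matrix(0, 4, 3))
  expect_equal(pbns$ad_value(pbns$ad_loss_softmax_ce(tape, lg, c(1, 2, 3, 1))),
               log(3), tolerance = 1e-12)
})

test_that("analytic loss gradients match finite differences on a toy model", {
  # 3-parameter linear model through each loss; <= 1e-4 relative
  set.seed(77)
  X <- matrix(rnorm(15), 5, 3)
  theta <- c(0.3, -0.2, 0.5)
  fd_check <- function(loss_of) {
    tape <- pbns$ad_tape()
    th <- pbns$ad_leaf(tape, matrix(theta, 3, 1))
    loss <- loss_of(tape, th)
    pbns$ad_backward(tape, loss)
    an <- th$grad
    eps <- 1e-6
    for (j in 1:3) {
      tp <- theta; tp[j] <- tp[j] + eps
      tm <- theta; tm[j] <- tm[j] - eps
      t2 <- pbns$ad_tape()
      lp <- pbns$ad_value(loss_of(t2, pbns$ad_leaf(t2, matrix(tp, 3, 1))))
      t3 <- pbns$ad_tape()
      lm <- pbns$ad_value(loss_of(t3, pbns$ad_leaf(t3, matrix(tm, 3, 1))))
      fd <- (lp - lm) / (2 * eps)
      expect_equal(an[j], fd, tolerance = 1e-4)
    }
  }
  y <- rnorm(5)
  fd_check(function(tape, th)
    pbns$ad_loss_mse(tape, pbns$ad_matmul(tape, X, th), matrix(y)))
  yb <- c(1, 0, 1, 1, 0)
  fd_check(function(tape, th)
    pbns$ad_loss_bce_logits(tape, pbns$ad_matmul(tape, X, th), yb))
  # softmax CE over two logit columns built from the same parameters
  cls <- c(1L, 2L, 1L, 2L, 1L)
  fd_check(function(tape, th) {
    z <- pbns$ad_matmul(tape, X, th)
    z2 <- pbns$ad_concat_cols(tape, z, pbns$ad_scale(tape, z, -1))
    pbns$ad_loss_softmax_ce(tape, z2, cls)
  })
  # residue-style weighted CE (weights 1/T per sequence)
  fd_check(function(tape, th) {
    z <- pbns$ad_matmul(tape, X, th)
    z2 <- pbns$ad_concat_cols(tape, z, pbns$ad_scale(tape, z, -0.5))
    pbns$ad_loss_softmax_ce(tape, z2, cls, weight = c(1/2, 1/2, 1/3, 1/3, 1/3))
  })
})

test_that("zero epochs returns the initialization unchanged", {
  task <- task_spec("t", "single", "sequence", "regression")
  recs <- tiny_records(12, task, seed = 1)
  split <- make_split(recs, c(0.5, 0.25, 0.25), seed = 1)
  m <- build_model("cnn", task, seed = 5)
  fit <- train(m, split, train_config(max_epochs = 0, seed = 1))
  expect_identical(fit$model$params, m$params)
  expect_identical(nrow(fit$history), 0L)
})

test_that("zero learning rate trains without changing the loss", {
  task <- task_spec("t", "single", "sequence", "regression")
  recs <- tiny_records(12, task, seed = 2)
  split <- make_split(recs, c(0.5, 0.25, 0.25), seed = 1)
  m <- build_model("cnn", task, seed = 5)
  # dropout disabled so every epoch sees the same deterministic forward
  fit <- train(m, split, train_config(learning_rate = 1e-12, max_epochs = 3,
                                      seed = 1, dropout = 0),
               eval_valid = FALSE)
  expect_equal(fit$history$train_loss[1L], fit$history$train_loss[3L],
               tolerance = 1e-6)
})

test_that("training is bit-deterministic given (data, config, seed)", {
  task <- task_spec("t", "single", "sequence", "binary")
  recs <- tiny_records(16, task, seed = 3)
  split <- make_split(recs, c(0.5, 0.25, 0.25), seed = 2)
  run <- function() {
    m <- build_model("cnn", task, seed = 4)
    train(m, split, train_config(max_epochs = 2, seed = 9))
  }
  f1 <- run(); f2 <- run()
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$params, f2$model$params)
  # and a different seed changes the trajectory
  m3 <- build_model("cnn", task, seed = 4)
  f3 <- train(m3, split, train_config(max_epochs = 2, seed = 10))
  expect_false(identical(f1$history$train_loss, f3$history$train_loss))
})

test_that("training loss decreases monotonically on the noise-free task", {
  task <- task_spec("t", "single", "sequence", "regression")
  recs <- generate_records(generator_spec(task, 120, length_range = c(20L, 40L),
                                          noise_sd = 0, seed = 6))
  split <- make_split(recs, seed = 1)
  m <- build_model("cnn", task, seed = 1)
  fit <- train(m, split, train_config(max_epochs = 8, seed = 1, dropout = 0),
               eval_valid = FALSE)
  l <- fit$history$train_loss
  expect_true(all(diff(l[3:8]) <= 1e-8))  # non-increasing after warm-up
  expect_true(all(is.finite(l)))
})

test_that("prediction tables are deterministic with one row per unit", {
  task <- task_spec("t", "single", "residue", "binary")
  recs <- tiny_records(4, task, seed = 7, flip_prob = 0)
  m <- build_model("cnn", task, seed = 1)
  p1 <- predict_records(m, recs)
  p2 <- predict_records(m, recs)
  expect_identical(p1, p2)
  expect_identical(nrow(p1),
                   sum(vapply(recs, function(r) nchar(r$sequence), integer(1))))
  expect_named(p1, c("id", "position", "pred_class", "prob.1", "prob.2"))
  # a length-9 sequence yields 9 keyed rows
  one <- validate_records(list(residue_record("z", "ACDEFGHIK", rep(0L, 9))),
                          task)
  pz <- predict_records(m, one)
  expect_identical(nrow(pz), 9L)
  expect_identical(pz$position, 1:9)
  # regression: one row per record
  rtask <- task_spec("t", "single", "sequence", "regression")
  rrecs <- tiny_records(5, rtask, seed = 8)
  mr <- build_model("cnn", rtask, seed = 1)
  expect_identical(nrow(predict_records(mr, rrecs)), 5L)
})

test_that("graph architectures train end to end on tiny data", {
  task <- task_spec("t", "single", "sequence", "binary")
  recs <- tiny_records(12, task, seed = 9, len = c(8L, 12L))
  split <- make_split(recs, c(0.5, 0.25, 0.25), seed = 1)
  for (a in c("gcn", "mpnn", "neuralfp")) {
    m <- build_model(a, task, seed = 1)
    fit <- train(m, split, train_config(max_epochs = 1, seed = 1),
                 eval_valid = FALSE)
    expect_true(is.finite(fit$history$train_loss), label = a)
    # frozen fingerprint encoder never changes
    if (a == "neuralfp") {
      expect_identical(fit$model$frozen, m$frozen)
    }
  }
})

test_that("checkpoints round-trip to identical predictions", {
  task <- task_spec("t", "single", "sequence", "binary")
  recs <- tiny_records(10, task, seed = 12)
  split <- make_split(recs, c(0.6, 0.2, 0.2), seed = 1)
  m <- build_model("cnn", task, seed = 2)
  fit <- train(m, split, train_config(max_epochs = 1, seed = 2),
               eval_valid = FALSE)
  f <- tempfile(fileext = ".rds")
  save_checkpoint(fit$model, f)
  back <- load_checkpoint(f)
  expect_identical(predict_records(back, recs),
                   predict_records(fit$model, recs))
  # fixed-embedding checkpoints demand their provider back
  prov <- embedding_provider("composition")
  mf <- build_model("fixed_embedding", task, provider = prov, seed = 1)
  f2 <- tempfile(fileext = ".rds")
  save_checkpoint(mf, f2)
  expect_error(load_checkpoint(f2), class = "pb_missing_provider")
  mf2 <- load_checkpoint(f2, provider = prov)
  expect_identical(predict_records(mf2, recs), predict_records(mf, recs))
})
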
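bin_task <- task_spec("b", "single", "sequence", "binary")
reg_task <- task_spec("g", "single", "sequence", "regression")
res_task <- task_spec("r", "single", "residue", "binary")
pair_reg <- task_spec("p", "pair", "sequence", "regression")

test_that("default configurations match the shipped golden file", {
  golden <- read.csv(system.file("extdata", "model_defaults.csv",
                                 package = "protbench"),
                     stringsAsFactors = FALSE,
                     colClasses = c(pooling = "character",
                                    conv_filters = "character",
                                    conv_kernels = "character"))
  golden[is.na(golden$pooling), "pooling"] <- ""
  dumped <- dump_default_configs()
  expect_equal(dumped, golden, ignore_attr = TRUE)
  # headline settings spelled out
  cnn <- model_config("cnn")
  expect_identical(cnn$hidden_dim, 256L)
  expect_identical(cnn$conv_filters, c(32L, 64L, 96L))
  expect_identical(cnn$conv_kernels, c(4L, 8L, 12L))
  expect_identical(cnn$pooling, "max")
  tr <- model_config("transformer")
  expect_identical(tr$n_layers, 2L)
  expect_identical(tr$n_heads, 4L)
  expect_identical(tr$hidden_dim, 64L)
  expect_identical(model_config("graphormer")$n_heads, 8L)
  expect_identical(model_config("mpnn")$n_layers, 6L)
  expect_equal(model_config("gcn")$learning_rate, 1e-5)
})

test_that("graph and fixed-embedding models refuse residue-level tasks", {
  for (a in c("gcn", "gat", "mpnn", "attentivefp", "fixed_embedding")) {
    expect_error(build_model(a, res_task,
                             provider = embedding_provider("composition")),
                 class = "pb_incompatible_architecture", label = a)
  }
  expect_s3_class(build_model("cnn", res_task), "pb_model")
})

test_that("forward output shapes follow the task contract", {
  recs <- tiny_records(6, bin_task, seed = 2)
  for (a in c("cnn", "cnn_gru", "transformer", "gcn", "mpnn")) {
    m <- build_model(a, bin_task, seed = 1)
    coll <- pbns$prepare_inputs(m, recs)
    out <- pbns$ad_value(pbns$pb_forward(m, coll(1:4))$out)
    expect_identical(dim(out), c(4L, 2L), label = a)
    expect_true(all(is.finite(out)), label = a)
  }
  m <- build_model("cnn", reg_task, seed = 1)
  rr <- tiny_records(5, reg_task, seed = 3)
  coll <- pbns$prepare_inputs(m, rr)
  expect_identical(dim(pbns$ad_value(pbns$pb_forward(m, coll(1:5))$out)),
                   c(5L, 1L))
  # residue: one logit row per padded position, C columns
  mr <- build_model("cnn", res_task, seed = 1)
  rres <- tiny_records(3, res_task, seed = 4, flip_prob = 0)
  coll <- pbns$prepare_inputs(mr, rres)
  b <- coll(1:3)
  out <- pbns$ad_value(pbns$pb_forward(mr, b)$out)
  expect_identical(dim(out), c(3L * ncol(b$mask), 2L))
})

test_that("all architectures produce finite outputs at default configs", {
  recs <- tiny_records(4, bin_task, seed = 5, len = c(8L, 12L))
  for (a in setdiff(protbench:::PB_ARCHITECTURES, "fixed_embedding")) {
    m <- build_model(a, bin_task, seed = 2)
    coll <- pbns$prepare_inputs(m, recs)
    out <- pbns$ad_value(pbns$pb_forward(m, coll(1:4))$out)
    expect_true(all(is.finite(out)), label = a)
  }
})

test_that("duplicated batch rows give identical eval-mode outputs", {
  recs <- tiny_records(4, bin_task, seed = 6)
  recs[[2L]] <- recs[[1L]]
  for (a in c("cnn", "transformer", "gcn")) {
    m <- build_model(a, bin_task, seed = 1)
    coll <- pbns$prepare_inputs(m, recs)
    out <- pbns$ad_value(pbns$pb_forward(m, coll(1:4))$out)
    expect_equal(out[1L, ], out[2L, ], tolerance = 1e-12, label = a)
  }
})

test_that("masked padding does not leak into valid outputs", {
  # the same record alone vs alongside a much longer one
  recs <- tiny_records(4, bin_task, seed = 7, len = c(10L, 12L))
  long <- tiny_records(1, bin_task, seed = 8, len = c(60L, 60L))
  for (a in c("cnn", "cnn_gru", "transformer")) {
    m <- build_model(a, bin_task, seed = 1)
    coll1 <- pbns$prepare_inputs(m, recs[1L])
    o1 <- pbns$ad_value(pbns$pb_forward(m, coll1(1L))$out)
    coll2 <- pbns$prepare_inputs(m, c(recs[1L], long))
    o2 <- pbns$ad_value(pbns$pb_forward(m, coll2(1:2))$out)
    expect_equal(o1[1L, ], o2[1L, ], tolerance = 1e-8, label = a)
  }
})

test_that("one GCN layer matches the dense normalized-propagation product", {
  # 3-node path graph, hand-set weights, dense matrix arithmetic oracle
  g <- structure(list(n_atoms = 3L, elements = c("C", "N", "O"),
                      atom_names = c("a", "b", "c"), residue_of = c(1L, 1L, 1L),
                      bonds = data.frame(from = c(1L, 2L), to = c(2L, 3L),
                                         order = "single")),
                 class = "pb_graph")
  gb <- pbns$batch_graphs(list(g))
  H <- matrix(c(1, 0.5, -1, 2, 0, 1), 3, 2)
  W <- matrix(c(0.3, -0.2, 0.7, 0.1, 0.5, -0.4), 2, 3)
  b <- c(0.1, -0.1, 0.2)
  tape <- pbns$ad_tape()
  ed <- pbns$gcn_edges(gb)
  out <- pbns$ad_value(pbns$gcn_layer(tape, pbns$ad_leaf(tape, H),
                                      pbns$ad_leaf(tape, W),
                                      pbns$ad_leaf(tape, b), ed, 3L))
  A <- matrix(0, 3, 3); A[1, 2] <- A[2, 1] <- A[2, 3] <- A[3, 2] <- 1
  At <- A + diag(3)
  Dt <- diag(1 / sqrt(rowSums(At)))
  expected <- Dt %*% At %*% Dt %*% sweep(H %*% W, 2, b, "+")
  expect_equal(out, expected, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("a single-node graph degenerates to the self-loop propagation", {
  g <- structure(list(n_atoms = 1L, elements = "C", atom_names = "a",
                      residue_of = 1L,
                      bonds = data.frame(from = integer(0), to = integer(0),
                                         order = character(0))),
                 class = "pb_graph")
  gb <- pbns$batch_graphs(list(g))
  H <- matrix(c(0.4, 1.2), 1, 2)
  W <- matrix(c(1, -1, 0.5, 0.25), 2, 2)
  tape <- pbns$ad_tape()
  ed <- pbns$gcn_edges(gb)
  out <- pbns$ad_value(pbns$gcn_layer(tape, pbns$ad_leaf(tape, H),
                                      pbns$ad_leaf(tape, W),
                                      pbns$ad_leaf(tape, c(0, 0)), ed, 1L))
  expect_equal(out, H %*% W, tolerance = 1e-12, ignore_attr = TRUE)  # A~ = I
})

test_that("graph-model outputs are invariant under node relabeling", {
  g <- sequence_to_peptide_graph("CWK")
  set.seed(31)
  for (a in c("gcn", "gat", "mpnn", "neuralfp", "attentivefp", "pagtn",
              "graphormer")) {
    m <- build_model(a, bin_task, seed = 3)
    perm <- sample(g$n_atoms)
    o1 <- pbns$ad_value(pbns$pb_forward(m, pbns$batch_graphs(list(g)))$out)
    o2 <- pbns$ad_value(pbns$pb_forward(
      m, pbns$batch_graphs(list(permute_graph(g, perm))))$out)
    expect_equal(o1, o2, tolerance = 1e-6, label = a)
  }
})

test_that("fixed-embedding heads honor the frozen-provider contract", {
  prov <- embedding_provider("random", dim = 8L, seed = 2)
  seqs <- c("ACDKW", "MMWCH")
  before <- lapply(seqs, prov$lookup)
  m <- build_model("fixed_embedding", pair_reg, provider = prov, seed = 1)
  # pair head input is the concatenation of the two provider vectors (16)
  expect_identical(nrow(m$params$mlp1_W), 16L)
  recs <- tiny_records(12, pair_reg, seed = 9)
  split <- make_split(recs, c(0.5, 0.25, 0.25), seed = 1)
  fit <- train(m, split, train_config(max_epochs = 2, seed = 1, dropout = 0),
               eval_valid = FALSE)
  after <- lapply(seqs, prov$lookup)
  expect_identical(before, after)  # bit-identical embeddings after training
  out <- predict_records(fit$model, recs)
  expect_identical(nrow(out), 12L)
  # same sequence always yields the same vector
  expect_identical(prov$lookup("ACDKW"), prov$lookup("ACDKW"))
})

test_that("sequence pair models concatenate in the given order", {
  m <- build_model("cnn", pair_reg, seed = 1)
  expect_identical(nrow(m$params$head_W), 2L * 256L)
  recs <- tiny_records(4, pair_reg, seed = 10)
  coll <- pbns$prepare_inputs(m, recs)
  out <- pbns$ad_value(pbns$pb_forward(m, coll(1:4))$out)
  expect_identical(dim(out), c(4L, 1L))
  # swapped sides change the output when the two sequences differ
  swapped <- lapply(recs, function(r)
    pair_record(r$id, r$sequence_b, r$sequence_a, r$label))
  coll2 <- pbns$prepare_inputs(m, swapped)
  out2 <- pbns$ad_value(pbns$pb_forward(m, coll2(1:4))$out)
  expect_false(isTRUE(all.equal(out, out2)))
})
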
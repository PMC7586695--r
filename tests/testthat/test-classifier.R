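tiny_setup <- function(n = 24, m = 2, seed = 42) {
  vocab <- c(letters[1:8], "<mol_a>", "<mol_b>", "<context>")
  tabs <- make_tables(vocab, dim = 6, seed = seed)
  set.seed(seed + 1)
  insts <- lapply(seq_len(n), function(i) {
    make_instance(relation_classes()[(i - 1) %% 8 + 1], vocab, m = m)
  })
  model <- mgnc_init(groups = c("N", "D", "K"), emb_dim = 6, m = m,
                     filter_lengths = c(2L, 3L), n_filters_ling = 4L,
                     n_filters_k = 3L, seed = seed)
  list(vocab = vocab, tabs = tabs, insts = insts, model = model)
}

test_that("forward produces a proper probability distribution over 8 classes", {
  st <- tiny_setup()
  probs <- mgnc_forward(st$model, st$insts[1:6], st$tabs)
  expect_equal(dim(probs), c(6L, 8L))
  expect_true(all(probs >= 0))
  expect_equal(rowSums(probs), rep(1, 6), tolerance = 1e-6)
  # eval-mode determinism
  expect_identical(probs, mgnc_forward(st$model, st$insts[1:6], st$tabs))
})

test_that("concatenated feature width follows the enabled groups", {
  # default filter counts: 3 x 100 per linguistic group + 50 knowledge
  mN <- mgnc_init(groups = "N", emb_dim = 6, m = 2, seed = 1)
  expect_equal(mN$n_feat, 300L)
  mNDK <- mgnc_init(groups = c("N", "D", "K"), emb_dim = 6, m = 2, seed = 1)
  expect_equal(mNDK$n_feat, 650L)
  st <- tiny_setup()
  # tiny config: 2 lengths x 4 filters per linguistic group + 3 knowledge
  feats <- mgnc_features(st$model, st$insts[1:2], st$tabs)
  expect_equal(ncol(feats), 2L * 4L + 2L * 4L + 3L)
})

test_that("padding beyond the true sentence never changes eval features", {
  st <- tiny_setup()
  inst <- st$insts[[1]]
  f1 <- mgnc_features(st$model, list(inst), st$tabs)
  padded <- inst
  padded$tokens <- c(inst$tokens, rep("<pad>", 7))
  f2 <- mgnc_features(st$model, list(padded), st$tabs)
  expect_equal(f1, f2, tolerance = 1e-12)
})

test_that("missing embedding table for an enabled group errors", {
  st <- tiny_setup()
  expect_error(mgnc_forward(st$model, st$insts[1], st$tabs["N"]),
               "missing embedding table")
})

test_that("training reduces loss and respects the group norm caps", {
  st <- tiny_setup(n = 48)
  cfg <- train_config(batch_size = 8L, max_epochs = 4L, seed = 3,
                      val_fraction = 0.2)
  fit <- finetune(st$model, st$insts, st$tabs, cfg)
  norms <- mgnc_group_norms(fit)
  expect_true(all(norms <= unlist(fit$lambda[fit$groups]) + 1e-8))
  # a tiny norm cap binds hard
  m2 <- st$model
  m2$lambda <- c(N = 0.001, D = 0.001, K = 0.001)
  fit2 <- finetune(m2, st$insts, st$tabs, cfg)
  expect_true(all(mgnc_group_norms(fit2) <= 0.001 + 1e-10))
})

test_that("norm projection holds after every optimizer step", {
  # instrument by stepping manually through two batches
  st <- tiny_setup(n = 16)
  enc <- ctxrel:::mgnc_encode(st$insts, st$model, st$tabs)
  model <- st$model
  model$lambda <- c(N = 0.05, D = 0.05, K = 0.05)
  model$params <- lapply(model$params, function(x) x + 0)
  am <- lapply(model$params, function(x) x * 0)
  av <- lapply(model$params, function(x) x * 0)
  for (stp in 1:6) {
    rows <- ((stp - 1) %% 2) * 8 + 1:8
    fwd <- ctxrel:::mgnc_forward_enc(model, enc, rows, cache = TRUE)
    gr <- ctxrel:::mgnc_backward(model, enc, rows, fwd, NULL)
    for (nm in names(gr)) {
      ctxrel:::adam_update_cpp(model$params[[nm]], gr[[nm]], am[[nm]],
                               av[[nm]], 0.05, stp, 0.9, 0.999, 1e-8)
    }
    model <- ctxrel:::mgnc_project(model)
    expect_true(all(mgnc_group_norms(model) <= 0.05 + 1e-10),
                info = paste("step", stp))
  }
})

test_that("zero epochs returns the initialized parameters unchanged", {
  st <- tiny_setup()
  fit <- finetune(st$model, st$insts, st$tabs,
                  train_config(batch_size = 4L, max_epochs = 0L, seed = 1))
  expect_identical(fit$params, st$model$params)
  expect_equal(attr(fit, "epochs_run"), 0L)
})

test_that("pretrain insists on context-free instances; empty corpora error", {
  st <- tiny_setup()
  expect_error(pretrain(st$model, st$insts, st$tabs), "context-free")
  expect_error(pretrain(st$model, list(), st$tabs), "empty corpus")
  expect_error(finetune(st$model, list(), st$tabs), "empty corpus")
  free <- lapply(st$insts, function(x) { x$corpus_kind <- "context-free"; x })
  fit <- pretrain(st$model, free, st$tabs,
                  train_config(batch_size = 50L, max_epochs = 1L, seed = 2))
  expect_s3_class(fit, "mgnc_model")
})

test_that("prediction breaks ties toward the canonical class order", {
  st <- tiny_setup()
  # force uniform probabilities: zero softmax weights and bias
  model <- st$model
  model$params$U[] <- 0
  model$params$b_out[] <- 0
  pred <- mgnc_predict(model, st$insts[1:5], st$tabs)
  expect_true(all(pred$labels == relation_classes()[1]))
  expect_true(all(pred$labels %in% relation_classes()))
})

test_that("training is reproducible for a fixed seed", {
  st <- tiny_setup(n = 32)
  cfg <- train_config(batch_size = 8L, max_epochs = 2L, seed = 11)
  f1 <- finetune(st$model, st$insts, st$tabs, cfg)
  f2 <- finetune(st$model, st$insts, st$tabs, cfg)
  expect_identical(f1$params, f2$params)
})

test_that("model checkpoints round-trip through JSON", {
  st <- tiny_setup()
  fit <- finetune(st$model, st$insts, st$tabs,
                  train_config(batch_size = 8L, max_epochs = 1L, seed = 2))
  tf <- tempfile(fileext = ".json")
  write_mgnc_model(fit, tf)
  back <- read_mgnc_model(tf)
  p1 <- mgnc_forward(fit, st$insts[1:3], st$tabs)
  p2 <- mgnc_forward(back, st$insts[1:3], st$tabs)
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("softmax normalization holds for random parameters and inputs", {
  set.seed(77)
  for (i in 1:5) {
    st <- tiny_setup(n = 4, seed = 100 + i)
    model <- st$model
    model$params$U[] <- rnorm(length(model$params$U), 0, 2)
    model$params$b_out[] <- rnorm(8, 0, 2)
    probs <- mgnc_forward(model, st$insts, st$tabs)
    expect_equal(rowSums(probs), rep(1, 4), tolerance = 1e-6)
    expect_true(all(probs >= 0))
  }
})
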
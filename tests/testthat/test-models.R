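test_that("benchmark architectures report their published parameter counts", {
  expect_equal(count_parameters(build_model("lstm")), 30979)
  expect_equal(count_parameters(build_model("gru")), 24515)
  expect_equal(count_parameters(build_model("cnn")), 97539)
  # the layer summary is consistent with the total
  m <- build_model("lstm")
  expect_equal(sum(summary(m)$params), count_parameters(m))
  # a bare 64 -> 3 readout layer: 64*3 + 3
  tail_dense <- summary(build_model("LSTM (64)-FC (3)",
                                    input = "sequence"))$params
  expect_equal(tail_dense[length(tail_dense)], 195)
})

test_that("analytic parameter formulas reproduce the counter", {
  set.seed(10)
  for (rep in 1:4) {
    Fd <- sample(5:60, 1); U <- sample(4:90, 1)
    lstm_n <- count_parameters(build_model(
      sprintf("LSTM (%d)-FC (3)", U), input_shape = c(20L, Fd),
      input = "sequence"))
    expect_equal(lstm_n, 4 * ((Fd + U) * U + U) + (U * 3 + 3))
    gru_n <- count_parameters(build_model(
      sprintf("GRU (%d)-FC (3)", U), input_shape = c(20L, Fd),
      input = "sequence"))
    expect_equal(gru_n, 3 * (Fd * U + U * U + 2 * U) + (U * 3 + 3))
  }
})

test_that("forward passes return a probability simplex of the right shape", {
  fs <- tiny_feature_set(2)
  for (name in c("lstm", "gru")) {
    m <- build_model(name, seed = 4)
    p <- predict(m, fs$features)
    expect_equal(dim(p), c(6L, 3L))
    expect_true(all(p >= 0))
    expect_equal(rowSums(as.matrix(p)), rep(1, 6), tolerance = 1e-6)
  }
  # resnet builds on (199, 39, 1) and is shape-stable across batch sizes
  m <- build_model("resnet", seed = 4)
  for (n in c(1, 3)) {
    p <- predict(m, fs$features[seq_len(n)])
    expect_equal(dim(p), c(n, 3L))
    expect_equal(rowSums(as.matrix(p)), rep(1, n), tolerance = 1e-6)
  }
})

test_that("builds and forward passes are deterministic under a seed", {
  fs <- tiny_feature_set(1)
  m1 <- build_model("gru", seed = 9)
  m2 <- build_model("gru", seed = 9)
  expect_identical(m1$layers, m2$layers)
  expect_identical(as.matrix(predict(m1, fs$features)),
                   as.matrix(predict(m2, fs$features)))
  m3 <- build_model("gru", seed = 10)
  expect_false(identical(m1$layers, m3$layers))
})

test_that("shape mismatches at a residual add are build errors", {
  expect_error(
    build_model("Conv [4, (3,3)]-residual {Conv [8, (1,1)]}-Conv [4, (3,3)]-add-GlobalAveragePooling ()",
                input_shape = c(12L, 9L), input = "image", n_classes = 4L),
    "mismatched shapes")
  expect_error(build_model("LSTM (64)-FC (5)", input = "sequence"),
               "3 class scores")
})

test_that("training reduces loss and predicts the class structure", {
  fs <- tiny_feature_set(6, seed = 2)
  m <- build_model("LSTM (8)-FC(8)-FC (3)", input = "sequence", seed = 2)
  fit <- train_model(m, fs$features, fs$labels, epochs = 8, batch_size = 6,
                     lr = 5e-3, seed = 2)
  h <- tidy(fit)
  expect_equal(nrow(h), 8)
  expect_lt(h$loss[8], h$loss[1])
  expect_gt(glance(fit)$accuracy, 0.9)
  # the scaler travels with the model into prediction
  expect_false(is.null(fit$model$scaler))
  pred <- predict(fit, fs$features, type = "class")
  expect_gt(mean(pred == fs$labels), 0.9)
})

test_that("a single training step decreases the loss across seeds and models", {
  # smoke property at learning rate 1e-3: one Adam step on one batch
  specs <- list(lstm = "lstm", gru = "gru", resnet = "resnet", cnn = "cnn")
  decreased <- logical(0)
  for (name in names(specs)) {
    for (seed in 1:5) {
      fs <- tiny_feature_set(2, seed = seed)
      m <- build_model(specs[[name]], seed = seed)
      # the property concerns the optimiser step; dropout noise between the
      # two loss evaluations would confound it
      for (i in seq_along(m$layers)) {
        if (m$layers[[i]]$kind == "dropout") m$layers[[i]]$rate <- 0
      }
      y <- match(fs$labels, c("normal", "abnormal", "noise"))
      scaler <- cardiomel:::fit_scaler(fs$features)
      feats <- cardiomel:::apply_scaler(fs$features, scaler)
      xb <- cardiomel:::assemble_batch(m, feats)
      fw0 <- cardiomel:::model_forward(m, xb, training = TRUE)
      l0 <- cardiomel:::xent_loss(fw0$logits, y)
      grads <- cardiomel:::model_backward(m, fw0$caches,
                                          cardiomel:::xent_grad(fw0$logits, y))
      opt <- cardiomel:::adam_init(m$layers)
      r <- cardiomel:::adam_step(m$layers, grads, opt, 1e-3, 1)
      m$layers <- r$layers
      fw1 <- cardiomel:::model_forward(m, xb, training = TRUE)
      l1 <- cardiomel:::xent_loss(fw1$logits, y)
      decreased <- c(decreased, l1 < l0)
    }
  }
  expect_gte(mean(decreased), 0.95)
})
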
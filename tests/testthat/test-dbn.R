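test_that("greedy pretraining chains layer sizes and feeds activations upward", {
  set.seed(2)
  X <- matrix(runif(80), 10, 8)
  cfg <- rbm_config(epochs = 3, batch_size = 5, seed = 9)
  dbn <- pretrain_dbn(X, c(4, 3), cfg)
  expect_equal(dbn$layer_sizes, c(8, 4, 3))
  expect_equal(dbn$state, "pretrained")
  expect_equal(dim(dbn$layers[[1]]$W), c(8, 4))
  expect_equal(dim(dbn$layers[[2]]$W), c(4, 3))

  # single-layer degeneracy: identical to a lone RBM under the derived seed
  cfg1 <- cfg; cfg1$seed <- epideep:::derive_seed(cfg$seed, 1L)
  lone <- train_rbm(X, 4, cfg1)
  dbn1 <- pretrain_dbn(X, 4, cfg)
  expect_equal(dbn1$layers[[1]]$W, lone$W)

  # propagated activations stay strictly inside (0, 1)
  act <- X
  for (l in seq_along(dbn$layers)) {
    act <- rbm_hidden_prob(act, dbn$layers[[l]])
    expect_true(all(act > 0 & act < 1))
  }
})

test_that("forward pass is deterministic and matches a scalar-loop oracle", {
  set.seed(5)
  dbn <- pretrain_dbn(matrix(runif(60), 10, 6), c(4, 3),
                      rbm_config(epochs = 2, batch_size = 5, seed = 5))
  net <- build_classifier(dbn, seed = 5)
  X <- matrix(runif(18), 3, 6)
  p <- dbn_forward(net, X)
  expect_true(all(p > 0 & p < 1))
  for (r in 1:3) {
    expect_equal(p[r], oracle_forward(net$W, net$bias, X[r, ]), tolerance = 1e-12)
  }
  # identical rows give identical outputs; zero net gives 0.5
  X2 <- X[c(1, 1, 2), ]
  p2 <- dbn_forward(net, X2)
  expect_equal(p2[1], p2[2])
  zero_net <- net
  zero_net$W <- lapply(net$W, function(w) w * 0)
  zero_net$bias <- lapply(net$bias, function(b) b * 0)
  expect_equal(dbn_forward(zero_net, X), rep(0.5, 3))
  expect_error(dbn_forward(net, X[, 1:3]), "expects")
})

test_that("analytic backprop gradients match central finite differences", {
  # random network with O(1) weights so no gradient sits at roundoff scale
  set.seed(8)
  net <- build_classifier(NULL, seed = 8, layer_sizes = c(5, 4, 3))
  net$W <- lapply(net$W, function(w) matrix(rnorm(length(w), sd = 0.8), nrow(w)))
  net$bias <- lapply(net$bias, function(b) rnorm(length(b), sd = 0.3))
  X <- matrix(runif(25), 5, 5)
  y <- c(1, 0, 1, 1, 0)
  g <- epideep:::bp_gradients(net, X, y)
  eps <- 1e-5
  loss_at <- function(n) epideep:::bp_gradients(n, X, y)$loss
  worst <- 0
  for (l in seq_along(net$W)) {
    for (idx in sample(length(net$W[[l]]), min(6, length(net$W[[l]])))) {
      np <- net; np$W[[l]][idx] <- np$W[[l]][idx] + eps
      nm <- net; nm$W[[l]][idx] <- nm$W[[l]][idx] - eps
      fd <- (loss_at(np) - loss_at(nm)) / (2 * eps)
      rel <- abs(fd - g$gW[[l]][idx]) / max(abs(fd) + abs(g$gW[[l]][idx]), 1e-8)
      worst <- max(worst, rel)
    }
    for (idx in seq_len(min(3, length(net$bias[[l]])))) {
      np <- net; np$bias[[l]][idx] <- np$bias[[l]][idx] + eps
      nm <- net; nm$bias[[l]][idx] <- nm$bias[[l]][idx] - eps
      fd <- (loss_at(np) - loss_at(nm)) / (2 * eps)
      rel <- abs(fd - g$gb[[l]][idx]) / max(abs(fd) + abs(g$gb[[l]][idx]), 1e-8)
      worst <- max(worst, rel)
    }
  }
  expect_lt(worst, 1e-5)
})

test_that("fine-tuning reduces training loss on a learnable task", {
  set.seed(3)
  n <- 60
  X <- matrix(runif(n * 6), n, 6)
  y <- as.integer(X[, 1] + X[, 2] > 1)   # linearly separable-ish rule
  dbn <- pretrain_dbn(X, c(5, 3), rbm_config(epochs = 5, batch_size = 10, seed = 3))
  net <- build_classifier(dbn, seed = 3)
  tuned <- finetune(net, X, y, finetune_config(epochs = 120, batch_size = 10,
                                               learning_rate = 0.5, seed = 3))
  expect_equal(tuned$state, "finetuned")
  expect_lt(tail(tuned$history, 1), tuned$history[1])

  # zero epochs leaves every parameter untouched
  frozen <- finetune(net, X, y, finetune_config(epochs = 0, seed = 3))
  expect_equal(frozen$W, net$W)
  expect_equal(frozen$bias, net$bias)

  expect_error(finetune(net, X, y[-1], finetune_config(epochs = 1)), "match")
  expect_error(finetune(net, X, y + 2, finetune_config(epochs = 1)), "binary")
})

test_that("prediction applies the documented threshold rule", {
  set.seed(4)
  dbn <- pretrain_dbn(matrix(runif(40), 10, 4), 3,
                      rbm_config(epochs = 2, batch_size = 5, seed = 4))
  net <- build_classifier(dbn, seed = 4)
  expect_error(predict(net, matrix(runif(8), 2, 4)), "fine-tuned")
  tuned <- finetune(net, matrix(runif(40), 10, 4), rep(c(0, 1), 5),
                    finetune_config(epochs = 3, seed = 4))
  X <- matrix(runif(12), 3, 4)
  pred <- predict(tuned, X)
  expect_equal(pred$label, as.integer(pred$probability >= 0.5))
  expect_true(all(predict(tuned, X, threshold = 0)$label == 1))
  # the boundary probability counts as positive
  fake <- tuned
  fake$W <- lapply(fake$W, function(w) w * 0)
  fake$bias <- lapply(fake$bias, function(b) b * 0)
  expect_equal(predict(fake, X, threshold = 0.5)$label, rep(1L, 3))
})

test_that("the whole classifier is deterministic under a fixed seed", {
  set.seed(10)
  X <- matrix(runif(100), 20, 5)
  y <- rep(c(0, 1), 10)
  cfg <- dbn_model_config(hidden_sizes = c(4, 3),
                          rbm = rbm_config(epochs = 3, batch_size = 5),
                          bp = finetune_config(epochs = 5, batch_size = 5),
                          seed = 77)
  m1 <- train_enhancer_model(X, y, cfg)
  m2 <- train_enhancer_model(X, y, cfg)
  expect_identical(m1, m2)
  expect_identical(predict(m1, X), predict(m2, X))
})
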
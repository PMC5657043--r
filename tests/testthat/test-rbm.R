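test_that("energy matches the bilinear formula and an elementwise oracle", {
  p0 <- rbm_params(matrix(0, 2, 2), c(0, 0), c(0, 0))
  for (v in oracle_configs(2)) for (h in oracle_configs(2)) {
    expect_equal(rbm_energy(v, h, p0), 0)
  }
  p1 <- rbm_params(matrix(1, 1, 1), b = 0, a = 0)
  expect_equal(rbm_energy(1, 1, p1), -1)
  for (seed in 1:5) {
    p <- random_tiny_rbm(3, 2, seed)
    set.seed(seed + 100)
    v <- rbinom(3, 1, 0.5); h <- rbinom(2, 1, 0.5)
    expect_equal(rbm_energy(v, h, p), oracle_energy(v, h, p$W, p$b, p$a))
  }
  expect_error(rbm_energy(c(1, 0), c(1), p1), "shape")
})

test_that("partition function equals exhaustive enumeration and refuses big models", {
  expect_equal(rbm_partition_function(rbm_params(matrix(0, 2, 1), c(0, 0), 0)), 8)
  expect_equal(rbm_partition_function(rbm_params(matrix(0, 3, 2), rep(0, 3), rep(0, 2))), 32)
  for (seed in 1:5) {
    p <- random_tiny_rbm(3, 2, seed)
    expect_equal(rbm_partition_function(p), oracle_partition(p$W, p$b, p$a),
                 tolerance = 1e-12)
  }
  expect_error(rbm_partition_function(rbm_params(matrix(0, 15, 6), rep(0, 15), rep(0, 6))),
               "refusing")
})

test_that("joint probabilities normalize and decrease with energy", {
  p0 <- rbm_params(matrix(0, 2, 1), c(0, 0), 0)
  expect_equal(rbm_joint_probability(c(1, 0), 1, p0), 1 / 8)
  for (seed in 1:8) {
    p <- random_tiny_rbm(sample(2:4, 1), sample(2:4, 1), seed)
    total <- 0
    for (v in oracle_configs(nrow(p$W))) for (h in oracle_configs(ncol(p$W))) {
      total <- total + rbm_joint_probability(v, h, p)
    }
    expect_equal(total, 1, tolerance = 1e-10)
  }
  # monotonicity: lower energy, higher probability
  p <- random_tiny_rbm(3, 2, 99)
  v1 <- c(1, 1, 0); h1 <- c(1, 0); v2 <- c(0, 1, 1); h2 <- c(0, 1)
  e1 <- rbm_energy(v1, h1, p); e2 <- rbm_energy(v2, h2, p)
  if (e1 < e2) {
    expect_gt(rbm_joint_probability(v1, h1, p), rbm_joint_probability(v2, h2, p))
  } else if (e2 < e1) {
    expect_gt(rbm_joint_probability(v2, h2, p), rbm_joint_probability(v1, h1, p))
  }
})

test_that("sigmoid conditionals equal enumeration-derived conditionals", {
  p0 <- rbm_params(matrix(0, 3, 2), rep(0, 3), rep(0, 2))
  expect_equal(rbm_hidden_prob(c(1, 0, 1), p0), c(0.5, 0.5))
  expect_equal(rbm_visible_prob(c(1, 0), p0), rep(0.5, 3))
  # saturation: huge hidden bias drives the conditional to 1
  psat <- rbm_params(matrix(0, 1, 1), 0, a = 50)
  expect_gte(rbm_hidden_prob(1, psat)[1], 1 - 1e-20)

  for (seed in 1:10) {
    n_v <- sample(2:5, 1); n_h <- sample(2:5, 1)
    p <- random_tiny_rbm(n_v, n_h, seed)
    set.seed(seed)
    v <- rbinom(n_v, 1, 0.5)
    h <- rbinom(n_h, 1, 0.5)
    expect_equal(rbm_hidden_prob(v, p),
                 oracle_hidden_conditional(v, p$W, p$b, p$a), tolerance = 1e-10)
    expect_equal(rbm_visible_prob(h, p),
                 oracle_visible_conditional(h, p$W, p$b, p$a), tolerance = 1e-10)
  }
})

test_that("conditionals are symmetric under transposing W and swapping biases", {
  p <- random_tiny_rbm(4, 3, 5)
  p_t <- rbm_params(t(p$W), b = p$a, a = p$b)
  v <- c(1, 0, 1, 1)
  expect_equal(rbm_hidden_prob(v, p), rbm_visible_prob(v, p_t))
})

test_that("cd_update respects the learning rate, determinism and input range", {
  p <- random_tiny_rbm(4, 3, 1)
  batch <- matrix(runif(12), 3, 4)
  cfg0 <- rbm_config(learning_rate = 0, momentum = 0, weight_decay = 0)
  set.seed(1); upd <- cd_update(batch, p, cfg0)
  expect_equal(upd$params$W, p$W)
  expect_equal(upd$params$b, p$b)
  expect_equal(upd$params$a, p$a)

  cfg <- rbm_config()
  set.seed(7); u1 <- cd_update(batch, p, cfg)
  set.seed(7); u2 <- cd_update(batch, p, cfg)
  expect_identical(u1$params, u2$params)

  expect_error(cd_update(batch * 2, p, cfg), "\\[0, 1\\]")
})

test_that("CD-1 weight gradient aligns with the exact log-likelihood gradient", {
  # 3-visible / 2-hidden RBM, 4-row dataset, 100 seeded batches
  p <- random_tiny_rbm(3, 2, 42, scale = 0.5)
  data <- matrix(c(1, 1, 0,
                   1, 0, 0,
                   0, 1, 1,
                   1, 1, 1), 4, 3, byrow = TRUE)
  exact <- oracle_loglik_gradient(data, p$W, p$b, p$a)
  cfg <- rbm_config(learning_rate = 1, momentum = 0, weight_decay = 0)
  cosines <- vapply(1:100, function(s) {
    set.seed(s)
    g <- cd_update(data, p, cfg)$grad
    sum(g * exact) / sqrt(sum(g^2) * sum(exact^2))
  }, numeric(1))
  expect_gt(mean(cosines), 0)
})

test_that("training increases exact likelihood and reduces reconstruction error", {
  patterns <- matrix(c(1, 1, 0, 0,
                       0, 0, 1, 1), 2, 4, byrow = TRUE)
  data <- patterns[rep(1:2, each = 4), ]
  cfg <- rbm_config(learning_rate = 0.2, epochs = 150, batch_size = 8,
                    momentum = 0.5, weight_decay = 0, seed = 3)
  init <- epideep:::init_rbm(4, 2, seed = cfg$seed)
  ll0 <- epideep:::rbm_exact_loglik(data, init)
  trained <- train_rbm(data, 2, cfg)
  ll1 <- epideep:::rbm_exact_loglik(data, trained)
  expect_gt(ll1, ll0)
  err <- attr(trained, "recon_error")
  expect_lt(err[length(err)], err[1])

  # determinism and empty-data contract
  expect_identical(train_rbm(data, 2, cfg), train_rbm(data, 2, cfg))
  expect_error(train_rbm(data[0, ], 2, cfg), "empty")
})
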
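test_that("single-key attention returns V and zero queries average V", {
  set.seed(1)
  V1 <- matrix(rnorm(3), 1, 3)
  expect_equal(scaled_dot_product_attention(matrix(rnorm(3), 1, 3),
                                            matrix(rnorm(3), 1, 3), V1), V1)
  Q0 <- matrix(0, 4, 2)
  K <- matrix(rnorm(8), 4, 2); V <- matrix(rnorm(8), 4, 2)
  out <- scaled_dot_product_attention(Q0, K, V, return_weights = TRUE)
  expect_equal(out$weights, matrix(0.25, 4, 4))
  expect_equal(out$output, matrix(colMeans(V), 4, 2, byrow = TRUE))
  expect_error(scaled_dot_product_attention(Q0, K, matrix(0, 3, 2)), "shape")
})

test_that("attention matches the loop-based oracle on random instances", {
  set.seed(7)
  for (i in 1:100) {
    m <- sample(2:8, 1); dk <- sample(1:8, 1)
    Q <- matrix(rnorm(m * dk), m, dk)
    K <- matrix(rnorm(m * dk), m, dk)
    V <- matrix(rnorm(m * dk), m, dk)
    res <- scaled_dot_product_attention(Q, K, V, return_weights = TRUE)
    expect_equal(res$output, oracle_sdpa(Q, K, V), tolerance = 1e-5)
    expect_true(all(res$weights >= 0))
    expect_equal(rowSums(res$weights), rep(1, m))
  }
})

test_that("multi-head attention matches an independent head-by-head oracle", {
  set.seed(11)
  for (i in 1:100) {
    m <- sample(2:8, 1); e <- sample(2:8, 1)
    dk <- sample(1:4, 1); h <- sample(1:4, 1)
    X <- matrix(rnorm(m * e), m, e)
    params <- random_mha_params(e, dk, h)
    expect_equal(multi_head_attention(X, params), oracle_mha(X, params),
                 tolerance = 1e-5)
  }
})

test_that("multi-head attention degenerates correctly", {
  set.seed(3)
  # one head with d_k = e reduces to plain scaled dot-product attention
  e <- 4; X <- matrix(rnorm(5 * e), 5, e)
  p <- random_mha_params(e, e, 1)
  p$Wo <- diag(e); p$bo <- numeric(e)
  Q <- X %*% p$heads[[1]]$Wq + rep(p$heads[[1]]$bq, each = 5)
  K <- X %*% p$heads[[1]]$Wk + rep(p$heads[[1]]$bk, each = 5)
  V <- X %*% p$heads[[1]]$Wv + rep(p$heads[[1]]$bv, each = 5)
  expect_equal(multi_head_attention(X, p), scaled_dot_product_attention(Q, K, V))
  # zero output projection: every row collapses to the bias
  p$Wo <- matrix(0, e, e); p$bo <- rnorm(e)
  out <- multi_head_attention(X, p)
  expect_equal(out, matrix(p$bo, 5, e, byrow = TRUE))
})

test_that("forward pass emits valid probabilities, deterministically", {
  cfg <- tiny_model_config()
  model <- init_transformer(cfg, seed = 42)
  set.seed(5)
  win <- array(rnorm(12 * 5 * 4), c(12, 5, 4))
  win[, , 2] <- win[, , 1]   # duplicate window
  probs <- transformer_forward(model, win)
  expect_equal(rowSums(probs), rep(1, 4), tolerance = 1e-6)
  expect_true(all(probs >= 0 & probs <= 1))
  expect_equal(probs[1, ], probs[2, ])
  # batch-order equivariance
  perm <- c(3, 1, 4, 2)
  expect_equal(transformer_forward(model, win[, , perm]), probs[perm, ])
  # repeated call is identical (inference mode has no randomness)
  expect_identical(transformer_forward(model, win), probs)
  expect_error(transformer_forward(model, array(0, c(5, 5, 1))), "expects")
})

test_that("closed-form parameter count matches the instantiated model", {
  # the published five-class architecture
  expect_equal(count_parameters(model_config()), 72645L)
  expect_equal(trunc(count_parameters(model_config()) / 10) / 100, 72.64)
  # head-only and single-block counts
  expect_equal(count_parameters(model_config(num_blocks = 0)), 16389L)
  expect_equal(count_parameters(model_config(num_blocks = 1)), 30453L)
  # closed form vs framework-style count over random configurations
  set.seed(9)
  for (i in 1:6) {
    cfg <- model_config(num_blocks = sample(0:3, 1), num_heads = sample(1:4, 1),
                        head_size = sample(1:8, 1), ff_width = sample(1:6, 1),
                        dense_units = sample(4:32, 1), num_classes = sample(2:5, 1),
                        input_steps = 10, input_channels = sample(3:8, 1))
    model <- init_transformer(cfg, seed = i)
    expect_equal(count_parameters(cfg), sum(vapply(model$params, length, 0L)))
    expect_equal(sum(describe_parameters(cfg)$count), count_parameters(cfg))
  }
})

test_that("hand-derived gradients match finite differences", {
  for (pre_norm in c(FALSE, TRUE)) {
    cfg <- model_config(num_blocks = 2, num_heads = 2, head_size = 3,
                        ff_width = 3, dense_units = 4, dropout_rate = 0,
                        num_classes = 3, input_steps = 6, input_channels = 4,
                        pre_norm = pre_norm)
    model <- init_transformer(cfg, seed = 7)
    set.seed(3)
    X <- matrix(rnorm(6 * 4), 6, 4)
    loss <- loss_config("focal", gamma = 2)
    fw <- eegformer:::.forward_window(model$params, cfg, X, cache = TRUE)
    dl <- eegformer:::loss_grad_logits(fw$probs, 2L, loss)
    g <- eegformer:::.backward_window(model$params, cfg, fw$cache, dl)
    h <- 1e-6
    for (pn in names(model$params)) {
      for (i in seq_len(min(length(model$params[[pn]]), 2L))) {
        pp <- model$params; pp[[pn]][i] <- pp[[pn]][i] + h
        lp <- eegformer:::loss_value(
          matrix(eegformer:::.forward_window(pp, cfg, X)$probs, 1), 2L, loss)
        pp[[pn]][i] <- pp[[pn]][i] - 2 * h
        lm <- eegformer:::loss_value(
          matrix(eegformer:::.forward_window(pp, cfg, X)$probs, 1), 2L, loss)
        expect_equal(g[[pn]][i], (lp - lm) / (2 * h), tolerance = 1e-3)
      }
    }
  }
})

test_that("sinusoidal positional encoding is parameter-free and changes the forward pass", {
  cfg0 <- tiny_model_config()
  cfg1 <- tiny_model_config(positional_encoding = "sinusoidal")
  expect_equal(count_parameters(cfg0), count_parameters(cfg1))
  m0 <- init_transformer(cfg0, seed = 2)
  m1 <- m0; m1$config <- cfg1
  set.seed(8)
  X <- array(rnorm(12 * 5), c(12, 5, 1))
  expect_false(isTRUE(all.equal(transformer_forward(m0, X),
                                transformer_forward(m1, X))))
})
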
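# Shared fixtures: small recordings, tiny model configs, and brute-force
# oracles kept deliberately independent of the package's vectorized
# implementations.

make_sine_recording <- function(freq, fs = 500, seconds = 4, channels = 2,
                                amp = 1) {
  t <- seq(0, seconds - 1 / fs, by = 1 / fs)
  data <- matrix(rep(amp * sin(2 * pi * freq * t), channels),
                 nrow = channels, byrow = TRUE)
  eeg_recording(data, fs = fs, subject_id = "sub-sine")
}

make_noise_recording <- function(fs = 500, seconds = 4, channels = 26,
                                 seed = 1, subject_id = "sub-noise",
                                 label = "MDD") {
  set.seed(seed)
  n <- as.integer(fs * seconds)
  eeg_recording(matrix(stats::rnorm(channels * n), channels, n),
                fs = fs, subject_id = subject_id, label = label)
}

tiny_model_config <- function(...) {
  model_config(num_blocks = 1L, num_heads = 2L, head_size = 4L,
               ff_width = 3L, dense_units = 8L, dropout_rate = 0,
               num_classes = 3L, input_steps = 12L, input_channels = 5L, ...)
}

# Loop-based scaled dot-product attention: explicit exp/normalize/weighted
# sum per query row.
oracle_sdpa <- function(Q, K, V) {
  m <- nrow(Q); dk <- ncol(Q)
  out <- matrix(0, m, dk)
  for (i in seq_len(m)) {
    scores <- numeric(m)
    for (j in seq_len(m)) scores[j] <- sum(Q[i, ] * K[j, ]) / sqrt(dk)
    w <- exp(scores - max(scores))
    w <- w / sum(w)
    for (j in seq_len(m)) out[i, ] <- out[i, ] + w[j] * V[j, ]
  }
  out
}

# Loop-based multi-head attention assembling each head by hand.
oracle_mha <- function(X, params) {
  m <- nrow(X)
  pieces <- list()
  for (p in params$heads) {
    Q <- matrix(0, m, ncol(p$Wq)); K <- Q; V <- Q
    for (i in seq_len(m)) {
      Q[i, ] <- drop(X[i, ] %*% p$Wq) + p$bq
      K[i, ] <- drop(X[i, ] %*% p$Wk) + p$bk
      V[i, ] <- drop(X[i, ] %*% p$Wv) + p$bv
    }
    pieces[[length(pieces) + 1L]] <- oracle_sdpa(Q, K, V)
  }
  Hcat <- do.call(cbind, pieces)
  out <- matrix(0, m, ncol(params$Wo))
  for (i in seq_len(m)) out[i, ] <- drop(Hcat[i, ] %*% params$Wo) + params$bo
  out
}

random_mha_params <- function(e, dk, h) {
  list(heads = lapply(seq_len(h), function(i)
         list(Wq = matrix(rnorm(e * dk), e, dk), bq = rnorm(dk),
              Wk = matrix(rnorm(e * dk), e, dk), bk = rnorm(dk),
              Wv = matrix(rnorm(e * dk), e, dk), bv = rnorm(dk))),
       Wo = matrix(rnorm(h * dk * e), h * dk, e), bo = rnorm(e))
}

# Count-and-argmax majority vote oracle; ties resolved by mean probability
# among tied classes, then lowest class index.
oracle_vote <- function(pred, probs, class_levels) {
  counts <- sapply(class_levels, function(cl) sum(pred == cl))
  top <- which(counts == max(counts))
  if (length(top) > 1L) {
    mp <- colMeans(probs)
    top <- top[mp[top] == max(mp[top])]
  }
  class_levels[min(top)]
}
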
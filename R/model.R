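#' Transformer classifier configuration
#'
#' Architecture hyper-parameters of the encoder-only transformer classifier.
#' Each encoder block applies multi-head scaled dot-product self-attention
#' and a point-wise feed-forward sub-layer, each wrapped in a residual
#' connection followed by layer normalization (post-norm). After the blocks,
#' features are averaged over the time axis and classified by a dense ReLU
#' layer and a softmax output.
#'
#' @param num_blocks Number of encoder blocks.
#' @param num_heads Attention heads per block.
#' @param head_size Per-head query/key/value dimension `d_k`.
#' @param ff_width Hidden width of the point-wise feed-forward sub-layer.
#' @param dense_units Width of the dense classification layer.
#' @param dropout_rate Dropout rate, applied after attention, inside the
#'   feed-forward sub-layer, and before the output layer; inactive at
#'   inference.
#' @param num_classes Number of diagnostic classes (5 or 3 in the study
#'   design).
#' @param input_steps Window length `m` in time steps.
#' @param input_channels Number of electrodes `e`.
#' @param pre_norm Use pre-norm blocks (layer-norm before each sub-layer)
#'   instead of the default post-norm; parameter count is unchanged.
#' @param positional_encoding `"none"` (default) or `"sinusoidal"`
#'   (parameter-free, added to the input).
#' @param ln_eps Layer-normalization variance floor.
#' @return A `model_config` list.
#' @export
model_config <- function(num_blocks = 4L, num_heads = 4L, head_size = 32L,
                         ff_width = 4L, dense_units = 512L,
                         dropout_rate = 0.25, num_classes = 5L,
                         input_steps = 1000L, input_channels = 26L,
                         pre_norm = FALSE,
                         positional_encoding = c("none", "sinusoidal"),
                         ln_eps = 1e-5) {
  positional_encoding <- match.arg(positional_encoding)
  cfg <- list(num_blocks = as.integer(num_blocks),
              num_heads = as.integer(num_heads),
              head_size = as.integer(head_size),
              ff_width = as.integer(ff_width),
              dense_units = as.integer(dense_units),
              dropout_rate = dropout_rate,
              num_classes = as.integer(num_classes),
              input_steps = as.integer(input_steps),
              input_channels = as.integer(input_channels),
              pre_norm = isTRUE(pre_norm),
              positional_encoding = positional_encoding,
              ln_eps = ln_eps)
  ints <- c("num_heads", "head_size", "ff_width", "dense_units",
            "num_classes", "input_steps", "input_channels")
  for (f in ints) if (cfg[[f]] < 1L) stop(f, " must be positive", call. = FALSE)
  if (cfg$num_blocks < 0L) stop("num_blocks must be >= 0", call. = FALSE)
  if (cfg$num_classes < 2L) stop("num_classes must be >= 2", call. = FALSE)
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("dropout_rate must be in [0, 1)", call. = FALSE)
  class(cfg) <- "model_config"
  cfg
}

.glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

#' Instantiate a transformer classifier
#'
#' Creates the full learnable parameter set (per-head Q/K/V projections with
#' bias, output projection, layer-norm gains/offsets, point-wise feed-forward
#' weights, dense head) with Glorot-uniform weight initialization and zero
#' biases.
#'
#' @param config A [model_config].
#' @param seed Integer seed for the weight initialization.
#' @return An object of class `transformer_classifier` with elements
#'   `config`, `params` (named list of numeric arrays) and
#'   `class_levels` (filled in by [train_transformer]).
#' @export
init_transformer <- function(config = model_config(), seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  e <- config$input_channels; dk <- config$head_size
  h <- config$num_heads; f <- config$ff_width
  du <- config$dense_units; C <- config$num_classes
  params <- list()
  with_seed(seed, {
    for (b in seq_len(config$num_blocks)) {
      for (i in seq_len(h)) {
        for (nm in c("Wq", "Wk", "Wv"))
          params[[sprintf("b%d.h%d.%s", b, i, nm)]] <- .glorot(e, dk)
        for (nm in c("bq", "bk", "bv"))
          params[[sprintf("b%d.h%d.%s", b, i, nm)]] <- numeric(dk)
      }
      params[[sprintf("b%d.Wo", b)]] <- .glorot(h * dk, e)
      params[[sprintf("b%d.bo", b)]] <- numeric(e)
      params[[sprintf("b%d.ln1.g", b)]] <- rep(1, e)
      params[[sprintf("b%d.ln1.b", b)]] <- numeric(e)
      params[[sprintf("b%d.W1", b)]] <- .glorot(e, f)
      params[[sprintf("b%d.b1", b)]] <- numeric(f)
      params[[sprintf("b%d.W2", b)]] <- .glorot(f, e)
      params[[sprintf("b%d.b2", b)]] <- numeric(e)
      params[[sprintf("b%d.ln2.g", b)]] <- rep(1, e)
      params[[sprintf("b%d.ln2.b", b)]] <- numeric(e)
    }
    params[["dense.W"]] <- .glorot(e, du)
    params[["dense.b"]] <- numeric(du)
    params[["out.W"]] <- .glorot(du, C)
    params[["out.b"]] <- numeric(C)
  })
  structure(list(config = config, params = params, class_levels = NULL,
                 init_seed = as.integer(seed)),
            class = "transformer_classifier")
}

#' @export
print.transformer_classifier <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("<transformer_classifier> %d block(s), %d head(s) x d_k=%d, ",
                     "ff %d, dense %d, %d classes, input %d x %d\n"),
              cfg$num_blocks, cfg$num_heads, cfg$head_size, cfg$ff_width,
              cfg$dense_units, cfg$num_classes, cfg$input_steps,
              cfg$input_channels))
  cat(sprintf("  trainable parameters: %s (%.2fk)\n",
              format(count_parameters(cfg), big.mark = ","),
              trunc(count_parameters(cfg) / 10) / 100))
  invisible(x)
}

.softmax_rows <- function(S) {
  E <- exp(S - apply(S, 1L, max))
  E / rowSums(E)
}

#' Scaled dot-product attention
#'
#' Computes `softmax(Q K' / sqrt(d_k)) V`. Each row of the attention matrix
#' is a probability vector over the keys.
#'
#' @param Q,K,V Numeric matrices of shape `m x d_k` (equal shapes).
#' @param return_weights Also return the `m x m` attention matrix.
#' @return The `m x d_k` attended values, or (with `return_weights`) a list
#'   with elements `output` and `weights`.
#' @export
scaled_dot_product_attention <- function(Q, K, V, return_weights = FALSE) {
  if (!all(dim(Q) == dim(K)) || !all(dim(Q) == dim(V)))
    stop("Q, K, V must share the same m x d_k shape", call. = FALSE)
  A <- .softmax_rows(Q %*% t(K) / sqrt(ncol(Q)))
  H <- A %*% V
  if (return_weights) list(output = H, weights = A) else H
}

#' Multi-head self-attention
#'
#' Projects the input to per-head queries, keys and values (`e -> d_k`, with
#' bias), applies [scaled_dot_product_attention] per head, concatenates the
#' head outputs and projects back to `e` dimensions.
#'
#' @param X Numeric `m x e` input matrix.
#' @param params List with one element `heads` (a list of `h` lists each
#'   holding `Wq, bq, Wk, bk, Wv, bv`) plus `Wo` (`h*d_k x e`) and `bo`.
#' @return The `m x e` attended representation.
#' @export
multi_head_attention <- function(X, params) {
  heads <- params$heads
  outs <- lapply(heads, function(p) {
    Q <- .affine(X, p$Wq, p$bq)
    K <- .affine(X, p$Wk, p$bk)
    V <- .affine(X, p$Wv, p$bv)
    scaled_dot_product_attention(Q, K, V)
  })
  Hcat <- do.call(cbind, outs)
  if (ncol(Hcat) != nrow(params$Wo))
    stop("output projection shape does not match h * d_k", call. = FALSE)
  .affine(Hcat, params$Wo, params$bo)
}

.affine <- function(X, W, b) {
  Y <- X %*% W
  Y + rep(b, each = nrow(Y))
}

.layernorm <- function(x, g, b, eps) {
  mu <- rowMeans(x)
  xc <- x - mu
  inv <- 1 / sqrt(rowMeans(xc^2) + eps)
  xhat <- xc * inv
  t(t(xhat) * g + b)
}

.relu <- function(x) (x > 0) * x

.sinusoidal_pe <- function(m, e) {
  pos <- seq_len(m) - 1
  i <- seq_len(e) - 1
  ang <- outer(pos, 1 / 10000^(2 * (i %/% 2) / e))
  pe <- matrix(0, m, e)
  even <- which(i %% 2 == 0)
  odd <- which(i %% 2 == 1)
  pe[, even] <- sin(ang[, even, drop = FALSE])
  pe[, odd] <- cos(ang[, odd, drop = FALSE])
  pe
}

.head_params <- function(params, b, h) {
  lapply(seq_len(h), function(i) list(
    Wq = params[[sprintf("b%d.h%d.Wq", b, i)]],
    bq = params[[sprintf("b%d.h%d.bq", b, i)]],
    Wk = params[[sprintf("b%d.h%d.Wk", b, i)]],
    bk = params[[sprintf("b%d.h%d.bk", b, i)]],
    Wv = params[[sprintf("b%d.h%d.Wv", b, i)]],
    bv = params[[sprintf("b%d.h%d.bv", b, i)]]))
}

# Forward pass for one m x e window. In training mode dropout masks are drawn
# from the current RNG stream; with cache = TRUE all intermediates needed by
# the backward pass are retained.
.forward_window <- function(params, cfg, X, training = FALSE, cache = FALSE) {
  eps <- cfg$ln_eps
  rate <- if (training) cfg$dropout_rate else 0
  drop_mask <- function(n) {
    if (rate <= 0) return(NULL)
    (stats::runif(n) >= rate) / (1 - rate)
  }
  if (cfg$positional_encoding == "sinusoidal")
    X <- X + .sinusoidal_pe(nrow(X), ncol(X))
  cc <- if (cache) list(X0 = X) else NULL
  blocks <- vector("list", cfg$num_blocks)
  for (b in seq_len(cfg$num_blocks)) {
    hp <- .head_params(params, b, cfg$num_heads)
    Xin <- X
    ln_in <- if (cfg$pre_norm)
      .layernorm(Xin, params[[sprintf("b%d.ln1.g", b)]],
                 params[[sprintf("b%d.ln1.b", b)]], eps) else Xin
    heads <- lapply(hp, function(p) {
      Q <- .affine(ln_in, p$Wq, p$bq)
      K <- .affine(ln_in, p$Wk, p$bk)
      V <- .affine(ln_in, p$Wv, p$bv)
      A <- .softmax_rows(Q %*% t(K) / sqrt(ncol(Q)))
      list(Q = Q, K = K, V = V, A = A, H = A %*% V)
    })
    Hcat <- do.call(cbind, lapply(heads, `[[`, "H"))
    O <- .affine(Hcat, params[[sprintf("b%d.Wo", b)]],
                 params[[sprintf("b%d.bo", b)]])
    mo <- drop_mask(length(O))
    Od <- if (is.null(mo)) O else O * mo
    R1 <- Xin + Od
    N1 <- if (cfg$pre_norm) R1
          else .layernorm(R1, params[[sprintf("b%d.ln1.g", b)]],
                          params[[sprintf("b%d.ln1.b", b)]], eps)
    ff_in <- if (cfg$pre_norm)
      .layernorm(N1, params[[sprintf("b%d.ln2.g", b)]],
                 params[[sprintf("b%d.ln2.b", b)]], eps) else N1
    pre1 <- .affine(ff_in, params[[sprintf("b%d.W1", b)]],
                    params[[sprintf("b%d.b1", b)]])
    F1 <- .relu(pre1)
    m1 <- drop_mask(length(F1))
    F1d <- if (is.null(m1)) F1 else F1 * m1
    F2 <- .affine(F1d, params[[sprintf("b%d.W2", b)]],
                  params[[sprintf("b%d.b2", b)]])
    R2 <- N1 + F2
    Xout <- if (cfg$pre_norm) R2
            else .layernorm(R2, params[[sprintf("b%d.ln2.g", b)]],
                            params[[sprintf("b%d.ln2.b", b)]], eps)
    if (cache)
      blocks[[b]] <- list(Xin = Xin, ln_in = ln_in, heads = heads,
                          Hcat = Hcat, O = O, mo = mo, R1 = R1, N1 = N1,
                          ff_in = ff_in, pre1 = pre1, m1 = m1, F1d = F1d,
                          R2 = R2)
    X <- Xout
  }
  pooled <- colMeans(X)
  pre_d <- drop(pooled %*% params$dense.W) + params$dense.b
  hd <- .relu(pre_d)
  md <- drop_mask(length(hd))
  hdd <- if (is.null(md)) hd else hd * md
  logits <- drop(hdd %*% params$out.W) + params$out.b
  z <- logits - max(logits)
  probs <- exp(z) / sum(exp(z))
  if (cache) {
    cc$blocks <- blocks
    cc$Xfinal <- X; cc$pooled <- pooled; cc$pre_d <- pre_d
    cc$hdd <- hdd; cc$md <- md; cc$probs <- probs
  }
  list(probs = probs, cache = cc)
}

#' Forward pass: class probabilities for a batch of windows
#'
#' Runs the classifier in inference mode (dropout off); deterministic given
#' fixed parameters. Each output row is a probability vector over classes.
#'
#' @param model A `transformer_classifier`.
#' @param windows A [window_set], an `m x e x n` array, or a single `m x e`
#'   matrix.
#' @return An `n x num_classes` matrix of class probabilities.
#' @export
transformer_forward <- function(model, windows) {
  stopifnot(inherits(model, "transformer_classifier"))
  cfg <- model$config
  win <- if (inherits(windows, "window_set")) windows$windows else windows
  if (is.matrix(win)) win <- array(win, dim = c(dim(win), 1L))
  d <- dim(win)
  if (d[1L] != cfg$input_steps || d[2L] != cfg$input_channels)
    stop(sprintf("windows are %d x %d but the model expects %d x %d",
                 d[1L], d[2L], cfg$input_steps, cfg$input_channels),
         call. = FALSE)
  out <- matrix(0, d[3L], cfg$num_classes)
  for (i in seq_len(d[3L]))
    out[i, ] <- .forward_window(model$params, cfg, win[, , i])$probs
  colnames(out) <- model$class_levels
  out
}

#' Count trainable parameters
#'
#' Closed-form count of the classifier's trainable parameters: per block,
#' `h` heads of three `e x d_k` projections with bias, an `h*d_k x e` output
#' projection with bias, two layer norms of `2e`, and the point-wise
#' feed-forward pair; plus the dense classification head. The default
#' five-class configuration has 72,645 parameters (72.64k).
#'
#' @param config A [model_config].
#' @return Integer parameter count.
#' @export
count_parameters <- function(config = model_config()) {
  sum(describe_parameters(config)$count)
}

#' Per-layer parameter table
#'
#' @param config A [model_config].
#' @return A data.frame with columns `layer` and `count`, one row per layer
#'   group, summing to [count_parameters].
#' @export
describe_parameters <- function(config = model_config()) {
  stopifnot(inherits(config, "model_config"))
  e <- config$input_channels; dk <- config$head_size
  h <- config$num_heads; f <- config$ff_width
  rows <- list()
  for (b in seq_len(config$num_blocks)) {
    rows[[length(rows) + 1L]] <- data.frame(
      layer = sprintf("block%d.attention (%d heads: Q,K,V %dx%d + W_O)", b, h, e, dk),
      count = h * 3L * (e * dk + dk) + (h * dk * e + e))
    rows[[length(rows) + 1L]] <- data.frame(
      layer = sprintf("block%d.layernorms", b), count = 2L * 2L * e)
    rows[[length(rows) + 1L]] <- data.frame(
      layer = sprintf("block%d.feedforward (%d-%d-%d)", b, e, f, e),
      count = (e * f + f) + (f * e + e))
  }
  rows[[length(rows) + 1L]] <- data.frame(
    layer = sprintf("head.dense (%d-%d)", e, config$dense_units),
    count = e * config$dense_units + config$dense_units)
  rows[[length(rows) + 1L]] <- data.frame(
    layer = sprintf("head.softmax (%d-%d)", config$dense_units, config$num_classes),
    count = config$dense_units * config$num_classes + config$num_classes)
  do.call(rbind, rows)
}
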
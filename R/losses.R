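#' Inverse-frequency class weights
#'
#' Computes per-class weights `W_i = N / (k * N_i)` from per-class sample
#' counts, where `N` is the total count and `k` the number of classes.
#' Balanced counts give all-ones weights, and the weights always satisfy
#' `sum_i (N_i / N) * W_i = 1`.
#'
#' @param counts Named (or unnamed) positive integer vector of per-class
#'   sample counts.
#' @return A named numeric vector of class `class_weights` with attributes
#'   `N` (total) and `k` (number of classes).
#' @export
compute_class_weights <- function(counts) {
  counts <- unlist(counts)
  if (length(counts) < 2L) stop("need at least two classes", call. = FALSE)
  if (any(counts <= 0))
    stop("class weight undefined: zero (or negative) count for class ",
         paste(which(counts <= 0), collapse = ", "), call. = FALSE)
  N <- sum(counts)
  k <- length(counts)
  w <- N / (k * counts)
  structure(w, N = N, k = k, class = c("class_weights", "numeric"))
}

# Normalize a (probs, targets) pair: probs must be n x k rows summing to 1;
# targets may be a one-hot matrix or an integer class-index vector.
.check_loss_inputs <- function(probs, targets) {
  if (!is.matrix(probs)) probs <- matrix(probs, nrow = 1L)
  k <- ncol(probs)
  if (is.matrix(targets)) {
    if (!all(dim(targets) == dim(probs)))
      stop("targets matrix must match the shape of probs", call. = FALSE)
    T <- targets
  } else {
    if (length(targets) != nrow(probs))
      stop("need one target per probability row", call. = FALSE)
    T <- one_hot(as.integer(targets), k)
  }
  list(P = pmin(pmax(probs, 1e-7), 1), T = T)
}

.reduce <- function(x, reduction) {
  switch(reduction, mean = mean(x), sum = sum(x),
         stop("unknown reduction: ", reduction, call. = FALSE))
}

#' Categorical cross-entropy loss
#'
#' Mean (or sum) over the batch of `-sum_i t_i log p_i` with natural
#' logarithms; probabilities are clipped to `[1e-7, 1]` before the log.
#'
#' @param probs `n x k` matrix of predicted class probabilities (rows sum
#'   to 1), or a single probability vector.
#' @param targets One-hot `n x k` matrix, or integer class indices (1-based)
#'   of length `n`.
#' @param reduction `"mean"` (default) or `"sum"` over the batch.
#' @return Non-negative scalar loss.
#' @export
cce_loss <- function(probs, targets, reduction = "mean") {
  z <- .check_loss_inputs(probs, targets)
  .reduce(-rowSums(z$T * log(z$P)), reduction)
}

#' Class-weighted categorical cross-entropy loss
#'
#' Cross-entropy with each sample's true-class term scaled by that class's
#' weight, `-sum_i W_i t_i log p_i`, penalizing misclassification of
#' minority classes. With all-ones weights this reduces to [cce_loss].
#'
#' @inheritParams cce_loss
#' @param weights Per-class weight vector of length `k`, typically from
#'   [compute_class_weights].
#' @return Non-negative scalar loss.
#' @export
wcce_loss <- function(probs, targets, weights, reduction = "mean") {
  if (missing(weights) || is.null(weights))
    stop("wcce_loss requires per-class weights", call. = FALSE)
  z <- .check_loss_inputs(probs, targets)
  if (length(weights) != ncol(z$P))
    stop("need one weight per class", call. = FALSE)
  .reduce(-rowSums(t(t(z$T) * as.numeric(weights)) * log(z$P)), reduction)
}

#' Focal loss
#'
#' Cross-entropy with the true-class term scaled by the modulating factor
#' `(1 - p)^gamma`, down-weighting well-classified (typically
#' majority-class) samples: `-sum_i t_i (1 - p_i)^gamma log p_i`.
#' With `gamma = 0` this equals [cce_loss]; the focal term is unweighted
#' unless `weights` is supplied explicitly.
#'
#' @inheritParams cce_loss
#' @param gamma Non-negative focusing parameter (2 by default; 0.5 is the
#'   other value used in the study design).
#' @param weights Optional per-class weights combined multiplicatively with
#'   the modulating factor (off by default).
#' @return Non-negative scalar loss.
#' @export
focal_loss <- function(probs, targets, gamma = 2, weights = NULL,
                       reduction = "mean") {
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma < 0)
    stop("gamma must be a single non-negative number", call. = FALSE)
  z <- .check_loss_inputs(probs, targets)
  W <- if (is.null(weights)) rep(1, ncol(z$P)) else as.numeric(weights)
  per <- -rowSums(t(t(z$T) * W) * (1 - z$P)^gamma * log(z$P))
  .reduce(per, reduction)
}

#' Loss configuration
#'
#' Selects the training objective: plain cross-entropy (`"cce"`),
#' class-weighted cross-entropy (`"wcce"`, weights derived from the training
#' split's label counts when not given), or focal loss (`"focal"`).
#'
#' @param kind One of `"cce"`, `"wcce"`, `"focal"`.
#' @param gamma Focusing parameter for the focal loss.
#' @param weights Optional [compute_class_weights] vector; required for
#'   `"wcce"` (auto-derived at training time when `NULL`).
#' @param reduction Batch reduction, `"mean"` or `"sum"`.
#' @return A `loss_config` list.
#' @export
loss_config <- function(kind = c("cce", "wcce", "focal"), gamma = 2,
                        weights = NULL, reduction = "mean") {
  kind <- match.arg(kind)
  if (gamma < 0) stop("gamma must be >= 0", call. = FALSE)
  structure(list(kind = kind, gamma = gamma, weights = weights,
                 reduction = reduction),
            class = "loss_config")
}

# Evaluate the configured loss on a batch.
loss_value <- function(probs, targets, loss) {
  switch(loss$kind,
         cce = cce_loss(probs, targets, loss$reduction),
         wcce = wcce_loss(probs, targets, loss$weights, loss$reduction),
         focal = focal_loss(probs, targets, loss$gamma, loss$weights,
                            loss$reduction))
}

# Gradient of the per-sample loss with respect to the softmax logits, for
# one probability vector p and one-hot target t. Derivations:
#   CCE:   dL/dz = p - t                     (scaled by W_c for WCCE)
#   focal: dL/dp_c = gamma (1-p_c)^(g-1) log p_c - (1-p_c)^g / p_c,
#          dL/dz_j = dL/dp_c * p_c (1[j=c] - p_j)
loss_grad_logits <- function(p, class_idx, loss) {
  k <- length(p)
  t <- numeric(k); t[class_idx] <- 1
  if (loss$kind == "cce") return(p - t)
  if (loss$kind == "wcce") return(loss$weights[class_idx] * (p - t))
  pc <- min(max(p[class_idx], 1e-7), 1 - 1e-12)
  g <- loss$gamma
  dLdpc <- g * (1 - pc)^(g - 1) * log(pc) - (1 - pc)^g / pc
  w <- if (is.null(loss$weights)) 1 else loss$weights[class_idx]
  dpc_dz <- pc * ((seq_len(k) == class_idx) - p)
  w * dLdpc * dpc_dz
}
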
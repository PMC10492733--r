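#' Stratified cross-individual subject split
#'
#' Partitions subjects into disjoint training/validation/test sets,
#' stratified by diagnostic label, so that every subject's windows land in
#' exactly one partition (the cross-individual guarantee) and each
#' partition's class mix tracks the cohort's. Deterministic under a fixed
#' seed. Classes with fewer than 3 subjects go entirely to training with a
#' warning.
#'
#' @param labels Named character vector mapping subject ID to label, or a
#'   participants data.frame with `subject_id` and `label` columns.
#' @param train,val,test Partition fractions, summing to 1.
#' @param seed Integer seed.
#' @return A `subject_split` list with character vectors `train`, `val`,
#'   `test`.
#' @export
split_subjects <- function(labels, train = 0.8, val = 0.1, test = 0.1,
                           seed = 1L) {
  if (is.data.frame(labels))
    labels <- stats::setNames(labels$label, labels$subject_id)
  if (is.null(names(labels)) || anyDuplicated(names(labels)))
    stop("`labels` must be named by unique subject IDs", call. = FALSE)
  if (abs(train + val + test - 1) > 1e-9)
    stop("partition fractions must sum to 1", call. = FALSE)
  parts <- list(train = character(0), val = character(0), test = character(0))
  with_seed(seed, {
    for (cl in sort(unique(labels))) {
      subs <- names(labels)[labels == cl]
      n <- length(subs)
      subs <- sample(subs)
      if (n < 3L) {
        warning(sprintf("class %s has only %d subject(s); assigning all to training", cl, n))
        parts$train <- c(parts$train, subs)
        next
      }
      n_te <- max(1L, round(n * test))
      n_va <- max(1L, round(n * val))
      parts$test <- c(parts$test, subs[seq_len(n_te)])
      parts$val <- c(parts$val, subs[n_te + seq_len(n_va)])
      parts$train <- c(parts$train, subs[(n_te + n_va + 1L):n])
    }
  })
  structure(list(train = parts$train, val = parts$val, test = parts$test,
                 fractions = c(train = train, val = val, test = test),
                 seed = as.integer(seed)),
            class = "subject_split")
}

#' @export
print.subject_split <- function(x, ...) {
  cat(sprintf("<subject_split> train %d / val %d / test %d subjects (seed %d)\n",
              length(x$train), length(x$val), length(x$test), x$seed))
  invisible(x)
}

#' Training configuration
#'
#' @param learning_rate Adam learning rate.
#' @param batch_size Windows per gradient step.
#' @param max_epochs Maximum training epochs.
#' @param patience Epochs without validation-accuracy improvement before
#'   early stopping.
#' @param beta1,beta2,epsilon Adam moment decays and stabilizer.
#' @param seed Seed for batch shuffling and dropout.
#' @param verbose Print per-epoch progress.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 5e-4, batch_size = 4L,
                         max_epochs = 100L, patience = 20L,
                         beta1 = 0.9, beta2 = 0.999, epsilon = 1e-7,
                         seed = 1L, verbose = FALSE) {
  cfg <- list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
              max_epochs = as.integer(max_epochs), patience = as.integer(patience),
              beta1 = beta1, beta2 = beta2, epsilon = epsilon,
              seed = as.integer(seed), verbose = isTRUE(verbose))
  if (learning_rate <= 0 || cfg$batch_size < 1L || cfg$max_epochs < 1L ||
      cfg$patience < 1L)
    stop("learning_rate, batch_size, max_epochs, patience must be positive",
         call. = FALSE)
  class(cfg) <- "train_config"
  cfg
}

#' Train the transformer classifier
#'
#' Minibatch Adam training of the window-level classifier with
#' early stopping and best-model checkpointing on validation accuracy.
#' Training and validation sets must be subject-disjoint; overlap is a hard
#' error (leakage guard). For the `"wcce"` objective, class weights are
#' derived from the training split's window label counts when not supplied.
#'
#' @param model A `transformer_classifier` from [init_transformer].
#' @param train_ws,val_ws Training and validation [window_set]s with labels.
#' @param loss A [loss_config].
#' @param config A [train_config].
#' @param class_levels Class label ordering; defaults to the sorted unique
#'   training labels.
#' @return The model with checkpointed best-validation parameters, plus
#'   elements `history` (per-epoch data.frame), `best_epoch`,
#'   `stopped_epoch`, and the resolved `loss`.
#' @export
train_transformer <- function(model, train_ws, val_ws,
                              loss = loss_config("cce"),
                              config = train_config(),
                              class_levels = NULL) {
  stopifnot(inherits(model, "transformer_classifier"),
            inherits(train_ws, "window_set"), inherits(val_ws, "window_set"))
  leak <- intersect(unique(train_ws$subject_id), unique(val_ws$subject_id))
  if (length(leak) > 0L)
    stop("subject leakage between training and validation sets: ",
         paste(utils::head(leak, 5L), collapse = ", "), call. = FALSE)
  if (n_windows(train_ws) == 0L) stop("empty training set", call. = FALSE)
  cfg <- model$config
  if (is.null(class_levels))
    class_levels <- sort(unique(train_ws$label))
  if (length(class_levels) != cfg$num_classes)
    stop(sprintf("model expects %d classes but training data has %d",
                 cfg$num_classes, length(class_levels)), call. = FALSE)
  y_tr <- match(train_ws$label, class_levels)
  y_va <- match(val_ws$label, class_levels)
  if (anyNA(y_tr) || anyNA(y_va))
    stop("labels outside class_levels in training/validation data", call. = FALSE)
  if (loss$kind == "wcce" && is.null(loss$weights))
    loss$weights <- as.numeric(compute_class_weights(
      table(factor(train_ws$label, levels = class_levels))))

  params <- model$params
  mom <- lapply(params, function(p) p * 0)
  vel <- mom
  n_tr <- n_windows(train_ws)
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     train_acc = numeric(0), val_loss = numeric(0),
                     val_acc = numeric(0))
  best <- list(acc = -Inf, params = params, epoch = 0L)
  wait <- 0L
  step <- 0L
  lr <- config$learning_rate
  b1 <- config$beta1; b2 <- config$beta2; eps <- config$epsilon

  eval_set <- function(ws, y) {
    n <- n_windows(ws)
    probs <- matrix(0, n, cfg$num_classes)
    for (i in seq_len(n))
      probs[i, ] <- .forward_window(params, cfg, ws$windows[, , i])$probs
    list(loss = loss_value(probs, y, loss),
         acc = mean(max.col(probs, ties.method = "first") == y))
  }

  with_seed(config$seed, {
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n_tr)
      ep_loss <- 0; ep_correct <- 0L
      for (start in seq(1L, n_tr, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, n_tr)]
        gacc <- NULL
        for (i in idx) {
          fw <- .forward_window(params, cfg, train_ws$windows[, , i],
                                training = TRUE, cache = TRUE)
          p <- fw$probs
          ep_loss <- ep_loss + loss_value(matrix(p, 1L), y_tr[i], loss)
          ep_correct <- ep_correct + (which.max(p) == y_tr[i])
          dlogits <- loss_grad_logits(p, y_tr[i], loss)
          g <- .backward_window(params, cfg, fw$cache, dlogits)
          gacc <- if (is.null(gacc)) g
                  else Map(`+`, gacc, g)
        }
        scale <- 1 / length(idx)
        step <- step + 1L
        corr <- lr * sqrt(1 - b2^step) / (1 - b1^step)
        for (nm in names(params)) {
          gn <- gacc[[nm]] * scale
          mom[[nm]] <- b1 * mom[[nm]] + (1 - b1) * gn
          vel[[nm]] <- b2 * vel[[nm]] + (1 - b2) * gn^2
          params[[nm]] <- params[[nm]] - corr * mom[[nm]] / (sqrt(vel[[nm]]) + eps)
        }
      }
      va <- eval_set(val_ws, y_va)
      hist[epoch, ] <- list(epoch, ep_loss / n_tr, ep_correct / n_tr,
                            va$loss, va$acc)
      if (config$verbose)
        message(sprintf("epoch %3d  train loss %.4f acc %.3f | val loss %.4f acc %.3f",
                        epoch, ep_loss / n_tr, ep_correct / n_tr, va$loss, va$acc))
      if (va$acc > best$acc) {
        best <- list(acc = va$acc, params = params, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }
  })
  model$params <- best$params
  model$class_levels <- class_levels
  model$history <- hist
  model$best_epoch <- best$epoch
  model$stopped_epoch <- nrow(hist)
  model$loss <- loss
  model$train_seed <- config$seed
  model
}

#' Window-level predictions
#'
#' Runs the model in inference mode over a window set, returning one
#' probability vector and one hard label per window. Argmax ties break
#' toward the lowest class index.
#'
#' @param model A trained `transformer_classifier` (with `class_levels`).
#' @param ws A [window_set].
#' @return A list with `probs` (n x k matrix), `pred` (character labels),
#'   `subject_id`, and `truth`.
#' @export
predict_windows <- function(model, ws) {
  if (is.null(model$class_levels))
    stop("model has no class_levels; train it first or set them", call. = FALSE)
  probs <- transformer_forward(model, ws)
  idx <- max.col(probs, ties.method = "first")
  list(probs = probs, pred = model$class_levels[idx],
       subject_id = ws$subject_id, truth = ws$label)
}

#' Patient-level majority vote
#'
#' Aggregates window-level predictions to one label per subject: the modal
#' predicted class, with ties broken by the highest per-subject mean softmax
#' probability among the tied classes, then by the lowest class index.
#'
#' @param pred Character vector of window-level predicted labels.
#' @param subject_id Subject ID per window.
#' @param probs Optional n x k probability matrix (for the tie rule and the
#'   `"mean_prob"` method).
#' @param class_levels Class label ordering; defaults to sorted unique
#'   predictions (or `colnames(probs)` when present).
#' @param method `"votes"` (default): modal hard label; `"mean_prob"`:
#'   argmax of the per-subject mean probability vector (requires `probs`).
#' @return A data.frame with columns `subject_id` and `pred`.
#' @export
majority_vote <- function(pred, subject_id, probs = NULL, class_levels = NULL,
                          method = c("votes", "mean_prob")) {
  method <- match.arg(method)
  stopifnot(length(pred) == length(subject_id))
  if (method == "mean_prob" && is.null(probs))
    stop("method = \"mean_prob\" requires the probability matrix", call. = FALSE)
  if (is.null(class_levels))
    class_levels <- if (!is.null(colnames(probs))) colnames(probs)
                    else sort(unique(pred))
  subs <- unique(subject_id)
  out <- character(length(subs))
  for (j in seq_along(subs)) {
    sel <- subject_id == subs[j]
    if (method == "mean_prob") {
      mp <- colMeans(probs[sel, , drop = FALSE])
      out[j] <- class_levels[which.max(mp)]
      next
    }
    votes <- table(factor(pred[sel], levels = class_levels))
    top <- which(votes == max(votes))
    if (length(top) > 1L && !is.null(probs)) {
      mp <- colMeans(probs[sel, , drop = FALSE])
      top <- top[mp[top] == max(mp[top])]
    }
    out[j] <- class_levels[min(top)]
  }
  data.frame(subject_id = subs, pred = out, stringsAsFactors = FALSE)
}

#' Classification metrics report
#'
#' Builds the confusion matrix (rows = truth, columns = predicted) and the
#' study's metric set: overall accuracy, one-vs-rest per-class precision
#' `TP/(TP+FP)` and recall `TP/(TP+FN)`, their macro means, and the F1 score
#' as the harmonic mean of macro precision and macro recall. A class absent
#' from both truth and prediction is reported as 0 and excluded from the
#' macro averages (with a message).
#'
#' @param truth,pred Equal-length label vectors.
#' @param class_levels Class label ordering.
#' @param level Tag: `"window"` or `"patient"`.
#' @return An `eval_report` list.
#' @export
evaluate_predictions <- function(truth, pred,
                                 class_levels = sort(unique(c(truth, pred))),
                                 level = c("window", "patient")) {
  level <- match.arg(level)
  stopifnot(length(truth) == length(pred))
  tf <- factor(truth, levels = class_levels)
  pf <- factor(pred, levels = class_levels)
  cm <- table(truth = tf, pred = pf)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  rec <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  present <- rowSums(cm) + colSums(cm) > 0
  if (any(!present))
    message("class(es) absent from both truth and prediction excluded from macro averages: ",
            paste(class_levels[!present], collapse = ", "))
  macro_p <- mean(prec[present])
  macro_r <- mean(rec[present])
  f1 <- if (macro_p + macro_r > 0) 2 * macro_p * macro_r / (macro_p + macro_r) else 0
  structure(list(level = level, confusion = unclass(cm),
                 accuracy = sum(tp) / length(truth),
                 precision = macro_p, recall = macro_r, f1 = f1,
                 per_class = data.frame(class = class_levels,
                                        precision = as.numeric(prec),
                                        recall = as.numeric(rec),
                                        support = as.numeric(rowSums(cm))),
                 n = length(truth)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s-level, n = %d\n", x$level, x$n))
  cat(sprintf("  accuracy %.4f | macro precision %.4f | macro recall %.4f | F1 %.4f\n",
              x$accuracy, x$precision, x$recall, x$f1))
  print(x$confusion)
  invisible(x)
}
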
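make_label_map <- function(n_per_class, classes = c("A", "B")) {
  labels <- rep(classes, times = n_per_class)
  stats::setNames(labels, sprintf("s%03d", seq_along(labels)))
}

test_that("subject split is disjoint, stratified and seed-deterministic", {
  labels <- make_label_map(c(50, 50))
  sp <- split_subjects(labels, seed = 1)
  expect_length(sp$train, 80)
  expect_length(sp$val, 10)
  expect_length(sp$test, 10)
  expect_length(intersect(sp$train, sp$val), 0)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_length(intersect(sp$val, sp$test), 0)
  sp2 <- split_subjects(labels, seed = 1)
  expect_identical(sp[c("train", "val", "test")], sp2[c("train", "val", "test")])
  expect_false(identical(sp$test, split_subjects(labels, seed = 2)$test))
})

test_that("split class proportions track the cohort within two subjects per class", {
  counts <- c(MDD = 426, ADHD = 271, SMC = 119, OCD = 75, Healthy = 47)
  labels <- make_label_map(counts, names(counts))
  sp <- split_subjects(labels, seed = 3)
  for (part in list(sp$val, sp$test)) {
    tab <- table(factor(labels[part], levels = names(counts)))
    expect_true(all(abs(tab - 0.1 * counts) <= 2))
  }
  tabtr <- table(factor(labels[sp$train], levels = names(counts)))
  expect_true(all(abs(tabtr - 0.8 * counts) <= 4))
  # tiny classes go to training with a warning
  expect_warning(sp2 <- split_subjects(make_label_map(c(10, 2))), "only 2")
  expect_true(all(names(which(make_label_map(c(10, 2)) == "B")) %in% sp2$train))
})

tiny_training_setup <- function(n_subj = 8, m = 12, e = 5, seed = 1) {
  # linearly separable toy windows: class shifts the channel means
  set.seed(seed)
  classes <- rep(c("A", "B", "C"), length.out = n_subj)
  sets <- lapply(seq_len(n_subj), function(i) {
    shift <- (match(classes[i], c("A", "B", "C")) - 2) * 2
    win <- array(rnorm(m * e * 4, mean = shift), c(m, e, 4))
    window_set(win, rep(sprintf("s%02d", i), 4), rep(classes[i], 4))
  })
  do.call(bind_window_sets, sets)
}

test_that("training checkpoints the best epoch and stops on patience", {
  ws <- tiny_training_setup(6)
  tr <- filter_subjects(ws, sprintf("s%02d", 1:3))
  va <- filter_subjects(ws, sprintf("s%02d", 4:6))
  model <- init_transformer(tiny_model_config(), seed = 1)
  fit <- train_transformer(model, tr, va, loss_config("cce"),
                           train_config(max_epochs = 30, patience = 2, seed = 1))
  expect_lte(fit$stopped_epoch, 30)
  expect_lte(fit$best_epoch + 2, fit$stopped_epoch + 2)  # checkpoint not after stop
  expect_equal(fit$history$epoch, seq_len(fit$stopped_epoch))
  expect_true(all(c("train_loss", "val_acc") %in% names(fit$history)))
  # checkpointed parameters are from the best epoch: retraining with
  # max_epochs = best_epoch reproduces them
  fit2 <- train_transformer(model, tr, va, loss_config("cce"),
                            train_config(max_epochs = fit$best_epoch,
                                         patience = fit$best_epoch, seed = 1))
  expect_equal(fit$params, fit2$params, tolerance = 1e-12)
})

test_that("training is deterministic under fixed seeds", {
  ws <- tiny_training_setup(6)
  tr <- filter_subjects(ws, sprintf("s%02d", 1:3))
  va <- filter_subjects(ws, sprintf("s%02d", 4:6))
  model <- init_transformer(tiny_model_config(), seed = 2)
  f1 <- train_transformer(model, tr, va, loss_config("cce"),
                          train_config(max_epochs = 4, patience = 4, seed = 9))
  f2 <- train_transformer(model, tr, va, loss_config("cce"),
                          train_config(max_epochs = 4, patience = 4, seed = 9))
  expect_identical(f1$history, f2$history)
  expect_identical(f1$params, f2$params)
})

test_that("the leakage guard rejects overlapping subject sets", {
  ws <- tiny_training_setup(4)
  model <- init_transformer(tiny_model_config(), seed = 1)
  expect_error(train_transformer(model, ws, ws, loss_config("cce"),
                                 train_config(max_epochs = 1)),
               "leakage")
})

test_that("window predictions break argmax ties toward the lowest class index", {
  model <- init_transformer(tiny_model_config(), seed = 1)
  model$class_levels <- c("A", "B", "C")
  # uniform probabilities: argmax tie -> class index 1
  expect_equal(max.col(matrix(1 / 3, 1, 3), ties.method = "first"), 1L)
  ws <- tiny_training_setup(3)
  pw <- predict_windows(model, ws)
  expect_equal(dim(pw$probs), c(n_windows(ws), 3L))
  expect_true(all(pw$pred %in% c("A", "B", "C")))
  idup <- which(ws$subject_id == ws$subject_id[1])
  expect_equal(length(pw$pred), n_windows(ws))
})

test_that("majority vote matches a count-and-argmax oracle, including ties", {
  set.seed(21)
  classes <- c("A", "B", "C", "D")
  for (i in 1:1000) {
    n <- sample(1:14, 1)
    pred <- sample(classes, n, replace = TRUE)
    probs <- matrix(stats::runif(n * 4), n, 4)
    probs <- probs / rowSums(probs)
    colnames(probs) <- classes
    got <- majority_vote(pred, rep("subj", n), probs, classes)
    expect_equal(got$pred, oracle_vote(pred, probs, classes))
  }
  # stated examples: strict majority, probability tie-break, unanimity
  expect_equal(majority_vote(c("A", "A", "B"), rep("s", 3),
                             class_levels = c("A", "B"))$pred, "A")
  pr <- rbind(c(0.6, 0.4), c(0.45, 0.55))
  colnames(pr) <- c("A", "B")
  expect_equal(majority_vote(c("A", "B"), c("s", "s"), pr, c("A", "B"))$pred, "A")
  expect_equal(majority_vote(rep("C", 14), rep("s", 14),
                             class_levels = c("A", "B", "C"))$pred, "C")
  # probability-sum aggregation can overturn a hard-vote majority
  pr2 <- rbind(c(0.34, 0.66), c(0.52, 0.48), c(0.51, 0.49))
  colnames(pr2) <- c("A", "B")
  hard <- majority_vote(c("B", "A", "A"), rep("s", 3), pr2, c("A", "B"))
  soft <- majority_vote(c("B", "A", "A"), rep("s", 3), pr2, c("A", "B"),
                        method = "mean_prob")
  expect_equal(hard$pred, "A")
  expect_equal(soft$pred, "B")
  expect_error(majority_vote("A", "s", method = "mean_prob"), "requires")
})

test_that("evaluation reproduces hand-computed confusion-matrix metrics", {
  perfect <- evaluate_predictions(c("A", "B", "A"), c("A", "B", "A"),
                                  c("A", "B"))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$f1, 1)
  # truth: A,A,B,B ; pred: A,B,B,B -> confusion [[1,1],[0,2]]
  rep2 <- evaluate_predictions(c("A", "A", "B", "B"), c("A", "B", "B", "B"),
                               c("A", "B"))
  expect_equal(unclass(rep2$confusion), matrix(c(1, 0, 1, 2), 2,
               dimnames = list(truth = c("A", "B"), pred = c("A", "B"))))
  expect_equal(rep2$accuracy, 0.75)
  expect_equal(rep2$per_class$precision, c(1, 2 / 3))
  expect_equal(rep2$per_class$recall, c(0.5, 1))
  expect_equal(rep2$precision, 5 / 6)
  expect_equal(rep2$recall, 0.75)
  expect_equal(rep2$f1, 2 * (5 / 6) * 0.75 / (5 / 6 + 0.75))
  # constant prediction on a balanced two-class set
  rep3 <- evaluate_predictions(c("A", "B", "A", "B"), rep("A", 4), c("A", "B"))
  expect_equal(rep3$accuracy, 0.5)
  # class absent from both truth and prediction is excluded from macros
  expect_message(rep4 <- evaluate_predictions(c("A", "B"), c("A", "B"),
                                              c("A", "B", "C")),
                 "excluded")
  expect_equal(rep4$precision, 1)
  expect_equal(sum(rep4$confusion), 2)
})
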
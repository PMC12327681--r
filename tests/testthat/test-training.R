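test_that("stratified file split follows the round-with-floor allocation", {
  files <- data.frame(file_id = sprintf("f%02d", 1:10),
                      label = rep(c("a", "b"), each = 5))
  sp <- stratified_file_split(files, 0.1, seed = 1)
  # round(0.5) would give 0; the floor rule forces 1 test file per class
  expect_length(sp$test_files, 2L)
  for (cl in c("a", "b")) {
    ids <- files$file_id[files$label == cl]
    expect_length(intersect(sp$test_files, ids), 1L)
  }
  # 40/5 class sizes -> 4 and 1 test files
  files2 <- data.frame(file_id = sprintf("g%02d", 1:45),
                       label = rep(c("healthy", "myxo"), c(40, 5)))
  sp2 <- stratified_file_split(files2, 0.1, seed = 3)
  lab2 <- files2$label[match(sp2$test_files, files2$file_id)]
  expect_equal(unname(table(lab2)["healthy"]), 4)
  expect_equal(unname(table(lab2)["myxo"]), 1)
  # partition law and determinism
  expect_setequal(c(sp2$train_files, sp2$test_files), files2$file_id)
  expect_identical(sp2, stratified_file_split(files2, 0.1, seed = 3))
  expect_false(identical(sp2$test_files,
                         stratified_file_split(files2, 0.1, seed = 4)$test_files))
  expect_error(stratified_file_split(
    data.frame(file_id = "only", label = "a"), 0.1, 1), "at least 2")
})

test_that("stratified k-fold partitions instances with balanced classes", {
  labels <- rep(c("a", "b"), each = 30)
  folds <- stratified_kfold(labels, k = 6, seed = 2)
  expect_length(folds, 6L)
  val_all <- sort(unlist(lapply(folds, `[[`, "val")))
  expect_identical(val_all, seq_along(labels))        # exact partition
  for (f in folds) {
    expect_identical(as.vector(table(labels[f$val])), c(5L, 5L))
    expect_setequal(c(f$train, f$val), seq_along(labels))
  }
  expect_identical(folds, stratified_kfold(labels, k = 6, seed = 2))
  # imbalanced labels: per-fold class counts within 1 of n_c/k
  set.seed(20)
  lab2 <- sample(rep(c("a", "b", "c"), c(25, 13, 41)))
  folds2 <- stratified_kfold(lab2, k = 6, seed = 5)
  for (f in folds2) {
    tab <- table(factor(lab2[f$val], levels = c("a", "b", "c")))
    expect_true(all(abs(tab - c(25, 13, 41) / 6) <= 1))
  }
  expect_error(stratified_kfold(c("a", "a", "b"), k = 2, seed = 1), "at least k")
})

test_that("file-grouped k-fold keeps all instances of a file in one fold", {
  file_ids <- rep(sprintf("f%02d", 1:12), each = 7)
  labels <- rep(rep(c("a", "b"), each = 6), each = 7)
  folds <- stratified_kfold(labels, k = 3, seed = 8, file_ids = file_ids)
  expect_identical(sort(unlist(lapply(folds, `[[`, "val"))), seq_along(labels))
  for (f in folds) {
    expect_length(intersect(unique(file_ids[f$val]), unique(file_ids[f$train])), 0L)
    # stratification: 2 files per class per val fold
    expect_identical(as.vector(table(labels[f$val])), c(14L, 14L))
  }
  expect_identical(folds, stratified_kfold(labels, 3, seed = 8, file_ids = file_ids))
  expect_error(stratified_kfold(labels, k = 7, seed = 1, file_ids = file_ids),
               "files")
})

test_that("class weights are inverse-frequency with weighted mean 1", {
  w <- class_weights(rep(c("a", "b"), c(30, 10)))
  expect_equal(unname(w), c(40 / (2 * 30), 40 / (2 * 10)))
  expect_equal(unname(w["b"]), 2)
  expect_equal(unname(class_weights(rep(c("x", "y"), each = 7))), c(1, 1))
  # sum_c n_c w_c = N for random count vectors
  set.seed(21)
  for (i in 1:10) {
    counts <- sample(1:50, sample(2:6, 1))
    labels <- rep(letters[seq_along(counts)], counts)
    w <- class_weights(labels)
    expect_equal(sum(counts * w), sum(counts))
  }
})

# A linear-model wrapper over the autodiff engine: cheap enough to train
# for many epochs in tests.
linear_toy_model <- function(D, K) {
  params <- list(W = msmce:::ad_param(matrix(0, D, K)),
                 b = msmce:::ad_param(rep(0, K)))
  list(params = params, states = list(),
       forward = function(X, mode = "eval") {
         msmce:::ad_add_rowvec(msmce:::ad_matmul(msmce:::as_ad(X), params$W),
                               params$b)
       })
}

toy_task <- function(n = 60, D = 5, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * D), n, D)
  y <- ifelse(X[, 1] + 0.5 * X[, 2] + rnorm(n, 0, 0.3) > 0, "pos", "neg")
  list(X = X, y = y)
}

test_that("train_model restores the best-epoch weights and keeps a consistent history", {
  task <- toy_task()
  cfg <- train_config(max_epochs = 15, batch_size = 16, seed = 3,
                      early_stop_patience = 10)
  model <- linear_toy_model(5, 2)
  fit <- train_model(model, task$X, task$y, 1:45, 46:60, cfg)
  h <- fit$history
  expect_true(all(c("epoch", "train_loss", "val_loss", "val_acc", "lr") %in% names(h)))
  expect_equal(fit$best_val_loss, min(h$val_loss))
  expect_equal(fit$best_epoch, h$epoch[which.min(h$val_loss)])
  # the restored model reproduces the recorded minimum val loss
  classes <- sort(unique(task$y))
  yi <- match(task$y, classes)
  w <- class_weights(task$y[1:45])
  ev <- msmce:::evaluate_loss(fit$model, task$X, yi, 46:60,
                              w[classes], cfg$batch_size)
  expect_equal(ev$loss, fit$best_val_loss, tolerance = 1e-10)
})

test_that("plateau scheduler decays lr by 0.1 after patience is exceeded; early stop halts", {
  # a model that cannot improve: zero gradients via frozen parameters
  task <- toy_task(n = 40, seed = 5)
  model <- linear_toy_model(5, 2)
  for (p in model$params) p$frozen <- TRUE
  cfg <- train_config(max_epochs = 64, batch_size = 16, seed = 4,
                      plateau_patience = 5, early_stop_patience = 10)
  fit <- train_model(model, task$X, task$y, 1:30, 31:40, cfg)
  h <- fit$history
  # epoch 1 improves over Inf; 6 stagnant epochs later the lr has dropped
  expect_equal(h$lr[1:7], rep(1e-3, 7))
  expect_equal(h$lr[8], 1e-4)
  # stopped by early stopping, not max_epochs
  expect_equal(nrow(h), 11)   # 1 improving + 10 stagnant
})

test_that("training runs to max_epochs when validation keeps improving", {
  task <- toy_task(n = 80, seed = 6)
  cfg <- train_config(max_epochs = 8, batch_size = 16, seed = 5)
  model <- linear_toy_model(5, 2)
  fit <- train_model(model, task$X, task$y, 1:60, 61:80, cfg)
  expect_equal(nrow(fit$history), 8)
})

test_that("training is deterministic under a fixed seed", {
  task <- toy_task(n = 50, seed = 7)
  cfg <- train_config(max_epochs = 5, batch_size = 16, seed = 11)
  f1 <- train_model(linear_toy_model(5, 2), task$X, task$y, 1:40, 41:50, cfg)
  f2 <- train_model(linear_toy_model(5, 2), task$X, task$y, 1:40, 41:50, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(get_weights(f1$model), get_weights(f2$model))
})

test_that("on balanced data, disabling class weights rescales the loss by a constant", {
  set.seed(22)
  X <- matrix(rnorm(40), 8, 5)
  y <- rep(1:2, each = 4)
  logits <- msmce:::ad_node(matrix(rnorm(16), 8, 2))
  l_w <- msmce:::ad_cross_entropy(logits, y, c(1, 1))
  l_u <- msmce:::ad_cross_entropy(logits, y, NULL)
  expect_equal(l_w$value, l_u$value)
  l_2 <- msmce:::ad_cross_entropy(logits, y, c(2, 2))
  expect_equal(l_2$value, l_u$value)   # weighted mean normalizes the scale out
})
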
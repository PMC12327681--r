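# Training protocol: file-level stratified hold-out, instance-level
# stratified k-fold cross-validation, class-weighted cross-entropy, Adam
# with L2 weight decay, plateau learning-rate decay and early stopping.
# All randomness flows from a single seed.

#' Training configuration
#'
#' @param test_frac fraction of files held out per class (default 0.10).
#' @param k number of cross-validation folds (default 6).
#' @param lr initial Adam learning rate (default 1e-3).
#' @param weight_decay L2 regularization coefficient (default 1e-5).
#' @param plateau_factor learning-rate decay factor on validation plateau
#'   (default 0.1).
#' @param plateau_patience epochs without improvement before decaying the
#'   learning rate (default 5).
#' @param early_stop_patience epochs without improvement before stopping
#'   (default 10).
#' @param max_epochs maximum training epochs (default 64).
#' @param batch_size minibatch size (default 64; 32 suits small
#'   multi-class sets).
#' @param seed integer seed controlling shuffling, init and dropout.
#' @return an object of class `train_config`.
#' @export
train_config <- function(test_frac = 0.10, k = 6L, lr = 1e-3,
                         weight_decay = 1e-5, plateau_factor = 0.1,
                         plateau_patience = 5L, early_stop_patience = 10L,
                         max_epochs = 64L, batch_size = 64L, seed = 1L) {
  stopifnot(test_frac > 0, test_frac < 1, k >= 2,
            plateau_patience >= 1, early_stop_patience >= 1, max_epochs >= 1)
  structure(list(test_frac = test_frac, k = as.integer(k), lr = lr,
                 weight_decay = weight_decay, plateau_factor = plateau_factor,
                 plateau_patience = as.integer(plateau_patience),
                 early_stop_patience = as.integer(early_stop_patience),
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed)),
            class = "train_config")
}

#' Stratified file-level hold-out split
#'
#' Per class, `round(test_frac * n_c)` files (never fewer than 1) are
#' assigned to the test set by seeded shuffle. Splitting at the file level
#' keeps all instances of one acquisition on the same side of the split.
#'
#' @param files data.frame with columns `file_id` and `label`, or a named
#'   character vector of labels (names = file ids).
#' @param test_frac test fraction (default 0.10).
#' @param seed integer seed.
#' @return list with `train_files` and `test_files` (character vectors).
#' @export
stratified_file_split <- function(files, test_frac = 0.10, seed = 1L) {
  if (!is.data.frame(files)) {
    files <- data.frame(file_id = names(files), label = unname(files))
  }
  stopifnot(all(c("file_id", "label") %in% names(files)))
  rng <- local_rng(seed)
  on.exit(rng())
  test_files <- character(0)
  for (cl in sort(unique(files$label))) {
    ids <- sort(files$file_id[files$label == cl])
    if (length(ids) < 2L) {
      stop("class '", cl, "' has ", length(ids),
           " file(s); at least 2 are needed to stratify a hold-out split")
    }
    n_test <- max(1L, round(test_frac * length(ids)))
    test_files <- c(test_files, sample(ids)[seq_len(n_test)])
  }
  list(train_files = sort(setdiff(files$file_id, test_files)),
       test_files = sort(test_files))
}

#' Stratified k-fold assignment of instances
#'
#' Instances of each class are shuffled (seeded) and dealt round-robin
#' across folds, so per-fold class proportions are within one instance of
#' the global proportions and the folds partition the instance set.
#'
#' @param labels instance labels.
#' @param k number of folds (default 6).
#' @param seed integer seed.
#' @param file_ids optional per-instance file ids. When given, whole files
#'   are assigned to folds (stratified by the file's label), so instances
#'   from one acquisition never straddle a fold boundary. Default NULL:
#'   plain instance-level stratification, matching the reference protocol.
#' @return list of `k` folds, each a list with `train` and `val` integer
#'   index vectors.
#' @export
stratified_kfold <- function(labels, k = 6L, seed = 1L, file_ids = NULL) {
  labels <- as.character(labels)
  rng <- local_rng(seed)
  on.exit(rng())
  assignment <- integer(length(labels))
  if (is.null(file_ids)) {
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      if (length(idx) < k) {
        stop("class '", cl, "' has ", length(idx),
             " instances; need at least k = ", k, " for stratified k-fold")
      }
      idx <- sample(idx)
      assignment[idx] <- rep_len(seq_len(k), length(idx))
    }
  } else {
    stopifnot(length(file_ids) == length(labels))
    file_ids <- as.character(file_ids)
    first <- !duplicated(file_ids)
    for (cl in sort(unique(labels[first]))) {
      fids <- file_ids[first][labels[first] == cl]
      if (length(fids) < k) {
        stop("class '", cl, "' has ", length(fids),
             " files; need at least k = ", k, " for file-grouped k-fold")
      }
      fids <- sample(fids)
      fold_of <- rep_len(seq_len(k), length(fids))
      for (i in seq_along(fids)) {
        assignment[file_ids == fids[i]] <- fold_of[i]
      }
    }
  }
  lapply(seq_len(k), function(f) {
    list(train = which(assignment != f), val = which(assignment == f))
  })
}

#' Inverse-frequency class weights
#'
#' `w_c = N / (K * n_c)`, so rarer classes weigh more and the
#' sample-weighted mean of the weights is 1 (`sum_c n_c w_c = N`).
#'
#' @param labels instance labels.
#' @return named numeric vector of per-class weights (sorted by class).
#' @export
class_weights <- function(labels) {
  tab <- table(as.character(labels))
  n <- sum(tab)
  w <- n / (length(tab) * as.numeric(tab))
  stats::setNames(w, names(tab))
}

# Seed the RNG reproducibly and restore the previous state on exit.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  set.seed(seed)
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}

# ---- optimizer -------------------------------------------------------------

adam_init <- function(params, lr, weight_decay) {
  list(lr = lr, weight_decay = weight_decay, beta1 = 0.9, beta2 = 0.999,
       eps = 1e-8, t = 0L,
       m = lapply(params, function(p) p$value * 0),
       v = lapply(params, function(p) p$value * 0))
}

adam_step <- function(opt, params) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (nm in names(params)) {
    p <- params[[nm]]
    if (isTRUE(p$frozen) || is.null(p$grad)) next
    g <- p$grad + opt$weight_decay * p$value
    opt$m[[nm]] <- opt$beta1 * opt$m[[nm]] + (1 - opt$beta1) * g
    opt$v[[nm]] <- opt$beta2 * opt$v[[nm]] + (1 - opt$beta2) * g^2
    p$value <- p$value - opt$lr * (opt$m[[nm]] / bc1) /
      (sqrt(opt$v[[nm]] / bc2) + opt$eps)
  }
  opt
}

# ---- training loop ---------------------------------------------------------

#' Train a model with Adam, plateau decay and early stopping
#'
#' Minimizes class-weighted cross-entropy on the training fold. When the
#' validation loss fails to improve for `plateau_patience` epochs the
#' learning rate is multiplied by `plateau_factor`; training stops after
#' `early_stop_patience` epochs without improvement or at `max_epochs`.
#' The weights of the best validation-loss epoch are restored before
#' returning. "Improvement" means any decrease in validation loss.
#'
#' @param model a trainable model ([baseline_model()], [compose()] or an
#'   ablation variant) with `$params`, `$states`, `$forward`.
#' @param X numeric instance matrix `[N x D]`.
#' @param y integer or factor labels (converted to `1..K` internally).
#' @param train_idx,val_idx row indices of the training and validation
#'   folds.
#' @param cfg a [train_config()].
#' @param weights optional per-class weights aligned with `sort(unique(y))`
#'   (default: [class_weights()] of the training fold).
#' @param verbose print one line per epoch.
#' @return list with `model` (best weights restored), `history`
#'   (data.frame: epoch, train_loss, val_loss, val_acc, lr), `best_epoch`
#'   and `best_val_loss`.
#' @export
train_model <- function(model, X, y, train_idx, val_idx, cfg,
                        weights = NULL, verbose = FALSE) {
  stopifnot(length(train_idx) > 0L, length(val_idx) > 0L)
  classes <- sort(unique(as.character(y)))
  yi <- match(as.character(y), classes)
  if (is.null(weights)) {
    w <- class_weights(y[train_idx])
    weights <- stats::setNames(numeric(length(classes)), classes)
    weights[names(w)] <- w
    weights[weights == 0] <- 1   # classes absent from the fold
  }
  rng <- local_rng(cfg$seed)
  on.exit(rng())
  opt <- adam_init(model$params, cfg$lr, cfg$weight_decay)
  best_val <- Inf
  best_epoch <- 0L
  best_w <- NULL
  plateau_bad <- 0L
  es_bad <- 0L
  hist <- list()
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample(train_idx)
    starts <- seq(1L, length(ord), by = cfg$batch_size)
    train_losses <- numeric(0)
    for (s in starts) {
      b <- ord[s:min(s + cfg$batch_size - 1L, length(ord))]
      if (length(b) < 2L) next   # batch statistics undefined for 1 sample
      logits <- model$forward(X[b, , drop = FALSE], "train")
      loss <- ad_cross_entropy(logits, yi[b], weights)
      if (!is.finite(loss$value)) {
        stop("non-finite training loss at epoch ", epoch,
             " (lr = ", opt$lr, "); check inputs or lower the learning rate")
      }
      ad_backward(loss)
      opt <- adam_step(opt, model$params)
      train_losses <- c(train_losses, loss$value)
    }
    ev <- evaluate_loss(model, X, yi, val_idx, weights, cfg$batch_size)
    hist[[epoch]] <- data.frame(epoch = epoch,
                                train_loss = mean(train_losses),
                                val_loss = ev$loss, val_acc = ev$acc,
                                lr = opt$lr)
    if (verbose) {
      message(sprintf("epoch %02d train %.4f val %.4f acc %.3f lr %g",
                      epoch, mean(train_losses), ev$loss, ev$acc, opt$lr))
    }
    if (ev$loss < best_val) {
      best_val <- ev$loss
      best_epoch <- epoch
      best_w <- get_weights(model)
      plateau_bad <- 0L
      es_bad <- 0L
    } else {
      plateau_bad <- plateau_bad + 1L
      es_bad <- es_bad + 1L
      if (plateau_bad > cfg$plateau_patience) {
        opt$lr <- opt$lr * cfg$plateau_factor
        plateau_bad <- 0L
      }
      if (es_bad >= cfg$early_stop_patience) break
    }
  }
  if (!is.null(best_w)) set_weights(model, best_w)
  list(model = model, history = do.call(rbind, hist),
       best_epoch = best_epoch, best_val_loss = best_val,
       classes = classes)
}

evaluate_loss <- function(model, X, yi, idx, weights, batch_size = 256L) {
  losses <- numeric(0)
  ns <- integer(0)
  correct <- 0L
  for (s in seq(1L, length(idx), by = batch_size)) {
    b <- idx[s:min(s + batch_size - 1L, length(idx))]
    logits <- model$forward(X[b, , drop = FALSE], "eval")
    loss <- ad_cross_entropy(logits, yi[b], weights)
    losses <- c(losses, loss$value)
    ns <- c(ns, length(b))
    correct <- correct + sum(max.col(logits$value, ties.method = "first") == yi[b])
  }
  list(loss = sum(losses * ns) / sum(ns), acc = correct / length(idx))
}

#' Predict class labels with a trained model
#'
#' @param model a trainable model.
#' @param X instance matrix.
#' @param classes class labels in training order (from [train_model()]'s
#'   return value); when NULL, integer indices are returned.
#' @param batch_size evaluation batch size.
#' @return predicted labels (character) or class indices (integer).
#' @export
predict_classes <- function(model, X, classes = NULL, batch_size = 256L) {
  n <- nrow(X)
  out <- integer(n)
  for (s in seq(1L, n, by = batch_size)) {
    b <- s:min(s + batch_size - 1L, n)
    logits <- model$forward(X[b, , drop = FALSE], "eval")
    out[b] <- max.col(logits$value, ties.method = "first")
  }
  if (is.null(classes)) out else classes[out]
}
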
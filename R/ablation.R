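# Component ablation ladder for the embedding module:
#   baseline            head on the raw instance vector
#   encoder             head on the global embedding E           [B x 1 x d]
#   channel_embedding   head on the conv channel stack C2        [B x C x d]
#   concatenation       head on the full concatenated output     [B x (1+C) x d]

ablation_variants <- c("baseline", "encoder", "channel_embedding", "concatenation")

#' Build one ablation-ladder model
#'
#' @param variant one of `"baseline"`, `"encoder"`, `"channel_embedding"`,
#'   `"concatenation"`.
#' @param cfg an [msmce_config()] (defines D and, for the non-baseline
#'   variants, the embedding dimensions).
#' @param n_classes number of classes.
#' @param family head family (default `"cnn1d"`).
#' @param ... extra [classifier_spec()] arguments (width, depth, ...).
#' @return a trainable model with `$forward(X [B x D], mode)`.
#' @export
ablation_model <- function(variant, cfg, n_classes, family = "cnn1d", ...) {
  variant <- match.arg(variant, ablation_variants)
  stopifnot(inherits(cfg, "msmce_config"))
  in_ch <- switch(variant, baseline = 1L, encoder = 1L,
                  channel_embedding = cfg$C, concatenation = 1L + cfg$C)
  spec <- classifier_spec(family = family, n_classes = n_classes,
                          in_channels = in_ch, ...)
  if (variant == "baseline") {
    m <- baseline_model(spec, cfg$D)
    m$variant <- variant
    return(m)
  }
  if (variant == "concatenation") {
    m <- compose(cfg, spec)
    m$variant <- variant
    return(m)
  }
  module <- msmce_init(cfg)
  head <- make_classifier(spec)
  seq_len_in <- if (variant == "encoder") 1L else cfg$C
  if (spec$family == "lstm") head$build(cfg$d)
  if (spec$family == "transformer") head$build(cfg$d, seq_len_in)
  head_params <- if (!is.null(head$env)) head$env$params else head$params
  keep <- if (variant == "encoder") {
    c("W1", "b1", "ln_gamma", "ln_beta", "W2", "b2")
  } else {
    names(module$params)
  }
  params <- c(stats::setNames(module$params[keep], paste0("msmce_", keep)),
              prefix_names(head_params, "head_"))
  states <- c(if (variant != "encoder") prefix_names(module$states, "msmce_"),
              prefix_names(head$states, "head_"))
  model <- list(spec = spec, msmce = module, head = head, cfg = cfg,
                D = cfg$D, params = params, states = states,
                kind = "ablation", variant = variant)
  model$forward <- function(X, mode = "eval") {
    E <- encoder_forward(X, module, mode)
    B <- nrow(E$value)
    x3 <- if (variant == "encoder") {
      ad_reshape(E, c(B, 1L, cfg$d))
    } else {
      channel_embed_forward(E, module, mode)
    }
    head$forward(x3, mode)
  }
  model
}

#' Run the four-variant ablation ladder
#'
#' Each variant is trained on the full training matrix (no k-fold
#' splitting; a fraction of the training instances is held back as the
#' early-stopping validation split) and evaluated on the hold-out matrix.
#'
#' @param train,test [feature_matrix()] objects (already normalized).
#' @param cfg an [msmce_config()] with `D = ncol(train$values)`.
#' @param tcfg a [train_config()].
#' @param family head family (default `"cnn1d"`).
#' @param val_frac fraction of training instances used as the validation
#'   split for early stopping (default 1/6, mirroring one CV fold).
#' @param ... extra [classifier_spec()] arguments.
#' @return data.frame with one row per variant: accuracy and macro-F1 on
#'   the hold-out set.
#' @export
run_ablation <- function(train, test, cfg, tcfg, family = "cnn1d",
                         val_frac = 1 / 6, ...) {
  stopifnot(ncol(train$values) == cfg$D)
  classes <- sort(unique(train$labels))
  rows <- vector("list", length(ablation_variants))
  for (i in seq_along(ablation_variants)) {
    v <- ablation_variants[i]
    rng <- local_rng(tcfg$seed + i)
    model <- ablation_model(v, cfg, length(classes), family = family, ...)
    rng()
    folds <- stratified_kfold(train$labels, k = max(2L, round(1 / val_frac)),
                              seed = tcfg$seed)
    fit <- train_model(model, train$values, train$labels,
                       folds[[1L]]$train, folds[[1L]]$val, tcfg)
    pred <- predict_classes(fit$model, test$values, fit$classes)
    cm <- confusion_matrix(test$labels, pred, levels = classes)
    mm <- macro_metrics(cm)
    rows[[i]] <- data.frame(variant = v, accuracy = mm$accuracy,
                            macro_f1 = mm$macro_f1,
                            best_epoch = fit$best_epoch)
  }
  do.call(rbind, rows)
}
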
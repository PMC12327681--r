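# The multi-channel embedding (MSMCE) module.
#
# A batch of single-channel spectrum vectors X [B x D] is transformed into
# a multi-channel representation O [B x (1+C) x d]:
#
#   H1 = Dropout(ReLU(LayerNorm(X W1 + b1)))     fully connected encoder
#   E  = H1 W2 + b2                              global embedding  [B x d]
#   E' = reshape(E)                              [B x 1 x d]
#   C1 = ReLU(BatchNorm(Conv1D(E', K1)))         channel expansion [B x C_mid x d]
#   C2 = Conv1D(Dropout(C1), K2)                 [B x C x d]
#   O  = Concat(E', C2)  along the channel axis  [B x (1+C) x d]
#
# Channel 0 of O is therefore the global embedding itself; channels 1..C
# are learned local feature maps over the embedding axis.

#' MSMCE hyperparameter configuration
#'
#' @param D input dimension (number of m/z bins).
#' @param hidden encoder hidden width (default 2048).
#' @param d embedding dimension (default 1024).
#' @param C number of output channels of the channel-embedding stack
#'   (default 256); the module output has `1 + C` channels.
#' @param C_mid intermediate convolution channels (default `C/2`).
#' @param kernel convolution kernel size, odd so "same" padding is exact
#'   (default 3).
#' @param dropout_p dropout probability for both the encoder and the
#'   convolutional dropout (default 0.3).
#' @return an object of class `msmce_config`.
#' @export
msmce_config <- function(D, hidden = 2048L, d = 1024L, C = 256L,
                         C_mid = max(1L, C %/% 2L), kernel = 3L,
                         dropout_p = 0.3) {
  stopifnot(D >= 1, hidden >= 1, d >= 1, C >= 1, C_mid >= 1,
            dropout_p >= 0, dropout_p < 1)
  if (kernel %% 2L != 1L) stop("kernel must be odd so the length axis is preserved exactly")
  structure(list(D = as.integer(D), hidden = as.integer(hidden),
                 d = as.integer(d), C = as.integer(C),
                 C_mid = as.integer(C_mid), kernel = as.integer(kernel),
                 dropout_p = dropout_p),
            class = "msmce_config")
}

# Fan-in uniform initialization, the convention of mainstream frameworks.
# Scalar `dims` yields a plain vector (bias), not a 1-d array.
init_uniform <- function(dims, fan_in) {
  b <- 1 / sqrt(fan_in)
  v <- stats::runif(prod(dims), -b, b)
  if (length(dims) > 1L) dim(v) <- dims
  v
}

#' Initialize MSMCE parameters
#'
#' Draws all learnable tensors (encoder weights, conv kernels and biases,
#' normalization affine parameters) from fan-in uniform distributions under
#' the current RNG state.
#'
#' @param cfg an [msmce_config()].
#' @return an object of class `msmce_module` holding `ad_param` nodes and
#'   the batch-norm running statistics.
#' @export
msmce_init <- function(cfg) {
  stopifnot(inherits(cfg, "msmce_config"))
  p <- list(
    W1 = ad_param(init_uniform(c(cfg$D, cfg$hidden), cfg$D)),
    b1 = ad_param(init_uniform(cfg$hidden, cfg$D)),
    ln_gamma = ad_param(rep(1, cfg$hidden)),
    ln_beta = ad_param(rep(0, cfg$hidden)),
    W2 = ad_param(init_uniform(c(cfg$hidden, cfg$d), cfg$hidden)),
    b2 = ad_param(init_uniform(cfg$d, cfg$hidden)),
    K1 = ad_param(init_uniform(c(cfg$C_mid, 1L, cfg$kernel), 1L * cfg$kernel)),
    K1_bias = ad_param(init_uniform(cfg$C_mid, 1L * cfg$kernel)),
    bn_gamma = ad_param(rep(1, cfg$C_mid)),
    bn_beta = ad_param(rep(0, cfg$C_mid)),
    K2 = ad_param(init_uniform(c(cfg$C, cfg$C_mid, cfg$kernel), cfg$C_mid * cfg$kernel)),
    K2_bias = ad_param(init_uniform(cfg$C, cfg$C_mid * cfg$kernel))
  )
  bn <- new.env(parent = emptyenv())
  bn$running_mean <- rep(0, cfg$C_mid)
  bn$running_var <- rep(1, cfg$C_mid)
  structure(list(cfg = cfg, params = p, states = list(bn = bn)),
            class = "msmce_module")
}

check_input_dim <- function(X, D) {
  v <- if (inherits(X, "ad_node")) X$value else X
  if (is.null(dim(v)) || length(dim(v)) != 2L) {
    stop("input must be a [batch x D] matrix")
  }
  if (ncol(v) != D) {
    stop("input dimension mismatch: expected D = ", D, " columns, got ", ncol(v))
  }
}

#' Encoder forward pass
#'
#' `E = Dropout(ReLU(LayerNorm(X W1 + b1))) W2 + b2`, layer normalization
#' over the hidden-feature axis per sample. Dropout is active only in
#' train mode; eval mode is deterministic.
#'
#' @param X numeric matrix `[B x D]` or `ad_node`.
#' @param module an [msmce_init()] module.
#' @param mode `"train"` or `"eval"`.
#' @return `ad_node` of shape `[B x d]`.
#' @export
encoder_forward <- function(X, module, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  check_input_dim(X, module$cfg$D)
  p <- module$params
  h <- ad_layernorm(ad_add_rowvec(ad_matmul(as_ad(X), p$W1), p$b1),
                    p$ln_gamma, p$ln_beta)
  h <- ad_dropout(ad_relu(h), module$cfg$dropout_p, mode)
  ad_add_rowvec(ad_matmul(h, p$W2), p$b2)
}

#' Channel-embedding forward pass
#'
#' Reshapes the global embedding to `[B x 1 x d]` and applies two 1-D
#' convolutions (1 -> C_mid -> C channels) with batch normalization, ReLU
#' and dropout between them; the length axis d is preserved.
#'
#' @param E numeric matrix `[B x d]` or `ad_node`.
#' @inheritParams encoder_forward
#' @return `ad_node` of shape `[B x C x d]`.
#' @export
channel_embed_forward <- function(E, module, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  E <- as_ad(E)
  cfg <- module$cfg
  p <- module$params
  B <- nrow(E$value)
  e3 <- ad_reshape(E, c(B, 1L, ncol(E$value)))
  c1 <- ad_relu(ad_batchnorm(ad_conv1d(e3, p$K1, p$K1_bias),
                             p$bn_gamma, p$bn_beta, module$states$bn, mode))
  ad_conv1d(ad_dropout(c1, cfg$dropout_p, mode), p$K2, p$K2_bias)
}

#' Full MSMCE forward pass
#'
#' Concatenates the global embedding (as channel 0) with the multi-channel
#' embedding along the channel axis.
#'
#' @inheritParams encoder_forward
#' @return `ad_node` of shape `[B x (1+C) x d]`; `O[, 1, ]` equals the
#'   encoder output exactly.
#' @export
msmce_forward <- function(X, module, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  E <- encoder_forward(X, module, mode)
  B <- nrow(E$value)
  e3 <- ad_reshape(E, c(B, 1L, module$cfg$d))
  c2 <- channel_embed_forward(E, module, mode)
  ad_concat_channels(e3, c2)
}

# ---- weight snapshot / restore (shared with classifier models) -------------

#' Snapshot all weights and normalization statistics of a model
#' @param model any object with `$params` (ad_param nodes) and `$states`.
#' @return a plain list, serializable with [save_checkpoint()].
#' @export
get_weights <- function(model) {
  list(params = lapply(model$params, function(p) p$value),
       states = lapply(model$states, function(s) as.list(s)))
}

#' Restore weights captured by [get_weights()]
#' @param model the model to restore into (modified in place).
#' @param w a weight snapshot.
#' @return `model`, invisibly.
#' @export
set_weights <- function(model, w) {
  stopifnot(identical(sort(names(model$params)), sort(names(w$params))))
  for (nm in names(w$params)) model$params[[nm]]$value <- w$params[[nm]]
  for (nm in names(w$states)) {
    for (k in names(w$states[[nm]])) model$states[[nm]][[k]] <- w$states[[nm]][[k]]
  }
  invisible(model)
}

#' Save a model checkpoint (weights + config) to a JSON file
#' @param model a model with `$params`/`$states`/`$cfg` or `$meta`.
#' @param path output path (JSON).
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  w <- get_weights(model)
  payload <- list(
    params = lapply(w$params, function(v) list(dim = dim_or_len(v), data = as.vector(v))),
    states = lapply(w$states, function(s) lapply(s, as.vector))
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' Load a checkpoint saved by [save_checkpoint()] into a model
#' @param model target model (must have identically shaped parameters).
#' @param path checkpoint path.
#' @return `model`, invisibly.
#' @export
load_checkpoint <- function(model, path) {
  payload <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  w <- list(
    params = lapply(payload$params, function(p) {
      v <- as.numeric(p$data)
      if (length(p$dim) > 1L) dim(v) <- p$dim
      v
    }),
    states = lapply(payload$states, function(s) lapply(s, as.numeric))
  )
  set_weights(model, w)
}

dim_or_len <- function(v) if (is.null(dim(v))) length(v) else dim(v)
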
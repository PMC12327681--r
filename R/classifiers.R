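# Classification heads and their input adaptations.
#
# Three small trainable families share one interface:
#   cnn1d        residual-style 1-D CNN over [B, channels, length]
#   lstm         recurrent head over [B, seq, feat], classifies from the
#                final hidden state
#   transformer  learned token embedding + CLS token + self-attention,
#                classifies from the CLS position
#
# Baseline models consume the raw instance vector (single channel /
# segmented sequence); MSMCE-composed models consume the [B, 1+C, d]
# module output, with channels treated as the sequence axis for the
# sequence families.

# ---- extra graph ops local to the heads ------------------------------------

# Slice time step t of a [B, L, F] tensor -> [B, F] matrix.
ad_step <- function(x, t) {
  x <- as_ad(x)
  dm <- dim(x$value)
  v <- x$value[, t, , drop = FALSE]
  dim(v) <- c(dm[1L], dm[3L])
  ad_node(v, list(x), function(g) {
    gr <- array(0, dm)
    gr[, t, ] <- g
    list(gr)
  })
}

ad_cbind <- function(nodes) {
  nodes <- lapply(nodes, as_ad)
  vals <- lapply(nodes, function(n) n$value)
  nc <- vapply(vals, ncol, 1L)
  ends <- cumsum(nc)
  starts <- ends - nc + 1L
  ad_node(do.call(cbind, vals), nodes, function(g) {
    lapply(seq_along(nodes), function(i) g[, starts[i]:ends[i], drop = FALSE])
  })
}

# Add a [Lp x F] matrix to each of B stacked [Lp x F] blocks of x.
ad_add_tiled <- function(x, p, B) {
  x <- as_ad(x); p <- as_ad(p)
  Lp <- nrow(p$value)
  tiled <- p$value[rep(seq_len(Lp), B), , drop = FALSE]
  ad_node(x$value + tiled, list(x, p), function(g) {
    gp <- Reduce(`+`, lapply(seq_len(B) - 1L, function(b) {
      g[b * Lp + seq_len(Lp), , drop = FALSE]
    }))
    list(g, gp)
  })
}

prefix_names <- function(lst, prefix) {
  if (length(lst) == 0L) return(stats::setNames(list(), character(0)))
  stats::setNames(lst, paste0(prefix, names(lst)))
}

linear_params <- function(prefix, n_in, n_out) {
  p <- list(ad_param(init_uniform(c(n_in, n_out), n_in)),
            ad_param(init_uniform(n_out, n_in)))
  names(p) <- paste0(prefix, c("_W", "_b"))
  p
}

ad_linear <- function(x, params, prefix) {
  ad_add_rowvec(ad_matmul(x, params[[paste0(prefix, "_W")]]),
                params[[paste0(prefix, "_b")]])
}

# ---- input adaptation ------------------------------------------------------

#' Segment instance vectors into a zero-padded sequence
#'
#' Row-major chunking of each length-`D` instance into `L = ceil(D /
#' segment_len)` chunks; the final chunk is zero-padded. Concatenating the
#' chunks (minus padding) restores the input.
#'
#' @param X numeric matrix `[B x D]`.
#' @param segment_len chunk length (>= 1).
#' @return numeric array `[B x L x segment_len]`.
#' @export
segment_sequence <- function(X, segment_len) {
  if (segment_len < 1) stop("segment_len must be >= 1")
  X <- as.matrix(X)
  B <- nrow(X); D <- ncol(X)
  L <- as.integer(ceiling(D / segment_len))
  pad <- L * segment_len - D
  if (pad > 0) X <- cbind(X, matrix(0, B, pad))
  # column-major fill: [B x (seg*L)] -> [B x seg x L] -> [B x L x seg]
  out <- array(X, c(B, segment_len, L))
  aperm(out, c(1L, 3L, 2L))
}

#' Specify a classification head
#'
#' @param family `"cnn1d"`, `"lstm"` or `"transformer"`.
#' @param n_classes number of classes (>= 2).
#' @param in_channels input channels (cnn1d; 1 for raw vectors, `1 + C`
#'   when fed MSMCE output).
#' @param segment_len chunk length used by the sequence baselines on raw
#'   vectors (default 1024).
#' @param width,depth cnn1d channel width and number of residual blocks.
#' @param hidden LSTM hidden size.
#' @param d_model,heads,n_layers,ff_mult transformer dimensions: model
#'   width (divisible by `heads`), attention heads, encoder layers and
#'   feed-forward expansion factor.
#' @param dropout_p head dropout probability.
#' @return an object of class `classifier_spec`.
#' @export
classifier_spec <- function(family = c("cnn1d", "lstm", "transformer"),
                            n_classes, in_channels = 1L, segment_len = 1024L,
                            width = 32L, depth = 1L, hidden = 128L,
                            d_model = 128L, heads = 4L, n_layers = 2L,
                            ff_mult = 2L, dropout_p = 0.1) {
  family <- match.arg(family)
  if (n_classes < 2) stop("n_classes must be >= 2")
  if (family == "transformer" && d_model %% heads != 0) {
    stop("transformer d_model (", d_model, ") must be divisible by heads (", heads, ")")
  }
  structure(list(family = family, n_classes = as.integer(n_classes),
                 in_channels = as.integer(in_channels),
                 segment_len = as.integer(segment_len),
                 width = as.integer(width), depth = as.integer(depth),
                 hidden = as.integer(hidden), d_model = as.integer(d_model),
                 heads = as.integer(heads), n_layers = as.integer(n_layers),
                 ff_mult = as.integer(ff_mult), dropout_p = dropout_p),
            class = "classifier_spec")
}

#' Build a classification head from a spec
#'
#' The returned model maps an adapted input tensor to class logits:
#' cnn1d consumes `[B, in_channels, L]`; lstm and transformer consume
#' `[B, seq, feat]`. Use [baseline_model()] / [compose()] for models that
#' consume raw instance vectors.
#'
#' @param spec a [classifier_spec()].
#' @return a model list with `$params`, `$states`, `$forward(x, mode)` and
#'   `$spec`.
#' @export
make_classifier <- function(spec) {
  stopifnot(inherits(spec, "classifier_spec"))
  switch(spec$family,
         cnn1d = make_cnn1d(spec),
         lstm = make_lstm(spec),
         transformer = make_transformer(spec))
}

# Residual-style 1-D CNN: stem conv -> `depth` residual blocks -> global
# average pooling -> linear head.
make_cnn1d <- function(spec) {
  w <- spec$width
  params <- list(
    stem_K = ad_param(init_uniform(c(w, spec$in_channels, 3L), spec$in_channels * 3L)),
    stem_b = ad_param(init_uniform(w, spec$in_channels * 3L)),
    stem_bn_g = ad_param(rep(1, w)), stem_bn_b = ad_param(rep(0, w))
  )
  states <- list(stem_bn = bn_state(w))
  for (i in seq_len(spec$depth)) {
    params[[paste0("res", i, "_K1")]] <- ad_param(init_uniform(c(w, w, 3L), w * 3L))
    params[[paste0("res", i, "_b1")]] <- ad_param(init_uniform(w, w * 3L))
    params[[paste0("res", i, "_bn1_g")]] <- ad_param(rep(1, w))
    params[[paste0("res", i, "_bn1_b")]] <- ad_param(rep(0, w))
    params[[paste0("res", i, "_K2")]] <- ad_param(init_uniform(c(w, w, 3L), w * 3L))
    params[[paste0("res", i, "_b2")]] <- ad_param(init_uniform(w, w * 3L))
    params[[paste0("res", i, "_bn2_g")]] <- ad_param(rep(1, w))
    params[[paste0("res", i, "_bn2_b")]] <- ad_param(rep(0, w))
    states[[paste0("res", i, "_bn1")]] <- bn_state(w)
    states[[paste0("res", i, "_bn2")]] <- bn_state(w)
  }
  params <- c(params, linear_params("head", w, spec$n_classes))
  model <- list(spec = spec, params = params, states = states)
  model$forward <- function(x, mode = "eval") {
    x <- as_ad(x)
    if (length(dim(x$value)) != 3L || dim(x$value)[2L] != spec$in_channels) {
      stop("cnn1d expects input [B x ", spec$in_channels, " x L], got shape [",
           paste(dim(x$value), collapse = " x "), "]")
    }
    h <- ad_relu(ad_batchnorm(ad_conv1d(x, params$stem_K, params$stem_b),
                              params$stem_bn_g, params$stem_bn_b,
                              states$stem_bn, mode))
    for (i in seq_len(spec$depth)) {
      r <- ad_relu(ad_batchnorm(
        ad_conv1d(h, params[[paste0("res", i, "_K1")]], params[[paste0("res", i, "_b1")]]),
        params[[paste0("res", i, "_bn1_g")]], params[[paste0("res", i, "_bn1_b")]],
        states[[paste0("res", i, "_bn1")]], mode))
      r <- ad_batchnorm(
        ad_conv1d(r, params[[paste0("res", i, "_K2")]], params[[paste0("res", i, "_b2")]]),
        params[[paste0("res", i, "_bn2_g")]], params[[paste0("res", i, "_bn2_b")]],
        states[[paste0("res", i, "_bn2")]], mode)
      h <- ad_relu(ad_add(h, r))
    }
    h <- ad_dropout(ad_gap(h), spec$dropout_p, mode)
    ad_linear(h, params, "head")
  }
  model
}

bn_state <- function(C) {
  e <- new.env(parent = emptyenv())
  e$running_mean <- rep(0, C)
  e$running_var <- rep(1, C)
  e
}

# Single-layer LSTM; feature size is inferred lazily from the first input
# so one head definition serves both segmented raw vectors and MSMCE
# channel sequences.
make_lstm <- function(spec) {
  H <- spec$hidden
  env <- new.env()
  env$params <- NULL
  model <- list(spec = spec, states = list())
  model$forward <- function(x, mode = "eval") {
    x <- as_ad(x)
    dm <- dim(x$value)
    if (length(dm) != 3L) stop("lstm expects input [B x seq x feat]")
    Fdim <- dm[3L]
    if (is.null(env$params)) {
      env$params <- c(
        list(Wx = ad_param(init_uniform(c(Fdim, 4L * H), H)),
             Wh = ad_param(init_uniform(c(H, 4L * H), H)),
             b = ad_param(init_uniform(4L * H, H))),
        linear_params("head", H, spec$n_classes)
      )
      model$params <<- env$params
    }
    p <- env$params
    if (nrow(p$Wx$value) != Fdim) {
      stop("lstm feature size mismatch: built for ", nrow(p$Wx$value),
           ", got ", Fdim)
    }
    B <- dm[1L]
    h <- ad_node(matrix(0, B, H))
    cc <- ad_node(matrix(0, B, H))
    for (t in seq_len(dm[2L])) {
      xt <- ad_step(x, t)
      gates <- ad_add_rowvec(ad_add(ad_matmul(xt, p$Wx), ad_matmul(h, p$Wh)), p$b)
      i_g <- ad_sigmoid(ad_cols(gates, seq_len(H)))
      f_g <- ad_sigmoid(ad_cols(gates, H + seq_len(H)))
      g_g <- ad_tanh(ad_cols(gates, 2L * H + seq_len(H)))
      o_g <- ad_sigmoid(ad_cols(gates, 3L * H + seq_len(H)))
      cc <- ad_add(ad_mul(f_g, cc), ad_mul(i_g, g_g))
      h <- ad_mul(o_g, ad_tanh(cc))
    }
    h <- ad_dropout(h, spec$dropout_p, mode)
    ad_linear(h, env$params, "head")
  }
  # materialize parameters for a declared feature size (profiling/training
  # need them before the first forward)
  model$build <- function(Fdim) {
    if (is.null(env$params)) model$forward(array(0, c(2L, 1L, Fdim)), "eval")
    env$params
  }
  model$env <- env
  model
}

# Pre-norm transformer encoder with a learnable CLS token and learned
# position embeddings; classification reads the CLS position.
make_transformer <- function(spec) {
  dm <- spec$d_model
  env <- new.env()
  env$params <- NULL
  env$seq_len <- NULL
  model <- list(spec = spec, states = list())
  build <- function(Fdim, L) {
    params <- c(
      linear_params("embed", Fdim, dm),
      list(cls = ad_param(init_uniform(c(1L, dm), dm)),
           pos = ad_param(init_uniform(c(L + 1L, dm), dm)))
    )
    for (l in seq_len(spec$n_layers)) {
      pre <- paste0("layer", l)
      params[[paste0(pre, "_ln1_g")]] <- ad_param(rep(1, dm))
      params[[paste0(pre, "_ln1_b")]] <- ad_param(rep(0, dm))
      params <- c(params,
                  linear_params(paste0(pre, "_q"), dm, dm),
                  linear_params(paste0(pre, "_k"), dm, dm),
                  linear_params(paste0(pre, "_v"), dm, dm),
                  linear_params(paste0(pre, "_o"), dm, dm))
      params[[paste0(pre, "_ln2_g")]] <- ad_param(rep(1, dm))
      params[[paste0(pre, "_ln2_b")]] <- ad_param(rep(0, dm))
      params <- c(params,
                  linear_params(paste0(pre, "_ff1"), dm, dm * spec$ff_mult),
                  linear_params(paste0(pre, "_ff2"), dm * spec$ff_mult, dm))
    }
    params[["final_ln_g"]] <- ad_param(rep(1, dm))
    params[["final_ln_b"]] <- ad_param(rep(0, dm))
    c(params, linear_params("head", dm, spec$n_classes))
  }
  model$forward <- function(x, mode = "eval") {
    x <- as_ad(x)
    dmx <- dim(x$value)
    if (length(dmx) != 3L) stop("transformer expects input [B x seq x feat]")
    B <- dmx[1L]; L <- dmx[2L]; Fdim <- dmx[3L]
    if (is.null(env$params)) {
      env$params <- build(Fdim, L)
      env$seq_len <- L
      model$params <<- env$params
    }
    p <- env$params
    if (env$seq_len != L || nrow(p$embed_W$value) != Fdim) {
      stop("transformer built for seq len ", env$seq_len, " x feat ",
           nrow(p$embed_W$value), ", got ", L, " x ", Fdim)
    }
    Lp <- L + 1L
    dh <- dm %/% spec$heads
    # column-major reshape of [B, L, F] puts row (b, t) at index b + (t-1)*B
    flat <- ad_reshape(x, c(B * L, Fdim))
    emb <- ad_linear(flat, p, "embed")
    blocks <- vector("list", B)
    for (b in seq_len(B)) {
      rows <- seq(b, by = B, length.out = L)
      blocks[[b * 2L]] <- ad_rows(emb, rows)
      blocks[[b * 2L - 1L]] <- p$cls
    }
    M <- ad_add_tiled(ad_rbind(blocks), p$pos, B)   # [(B*Lp) x dm]
    for (l in seq_len(spec$n_layers)) {
      pre <- paste0("layer", l)
      Mn <- ad_layernorm(M, p[[paste0(pre, "_ln1_g")]], p[[paste0(pre, "_ln1_b")]])
      Q <- ad_linear(Mn, p, paste0(pre, "_q"))
      K <- ad_linear(Mn, p, paste0(pre, "_k"))
      V <- ad_linear(Mn, p, paste0(pre, "_v"))
      outs <- vector("list", B)
      for (b in seq_len(B)) {
        rows <- (b - 1L) * Lp + seq_len(Lp)
        hb <- vector("list", spec$heads)
        for (h in seq_len(spec$heads)) {
          cols <- (h - 1L) * dh + seq_len(dh)
          Qb <- ad_cols(ad_rows(Q, rows), cols)
          Kb <- ad_cols(ad_rows(K, rows), cols)
          Vb <- ad_cols(ad_rows(V, rows), cols)
          A <- ad_softmax_rows(ad_scale(ad_matmul(Qb, ad_t(Kb)), 1 / sqrt(dh)))
          hb[[h]] <- ad_matmul(A, Vb)
        }
        outs[[b]] <- ad_cbind(hb)
      }
      att <- ad_dropout(ad_linear(ad_rbind(outs), p, paste0(pre, "_o")),
                        spec$dropout_p, mode)
      M <- ad_add(M, att)
      Mn <- ad_layernorm(M, p[[paste0(pre, "_ln2_g")]], p[[paste0(pre, "_ln2_b")]])
      ff <- ad_linear(ad_dropout(ad_relu(ad_linear(Mn, p, paste0(pre, "_ff1"))),
                                 spec$dropout_p, mode),
                      p, paste0(pre, "_ff2"))
      M <- ad_add(M, ff)
    }
    M <- ad_layernorm(M, p$final_ln_g, p$final_ln_b)
    cls_rows <- (seq_len(B) - 1L) * Lp + 1L
    ad_linear(ad_rows(M, cls_rows), p, "head")
  }
  model$build <- function(Fdim, L) {
    if (is.null(env$params)) {
      env$params <- build(Fdim, L)
      env$seq_len <- L
      model$params <<- env$params
    }
    env$params
  }
  model$env <- env
  model
}

# ---- raw-input baselines and MSMCE composition -----------------------------

#' Wrap a head into a baseline model over raw instance vectors
#'
#' cnn1d sees the instance as a single channel `[B x 1 x D]`; sequence
#' families see it segmented into `segment_len` chunks.
#'
#' @param spec a [classifier_spec()] (cnn1d must have `in_channels = 1`).
#' @param D instance dimension.
#' @return a trainable model with `$forward(X [B x D], mode)`.
#' @export
baseline_model <- function(spec, D) {
  if (spec$family == "cnn1d" && spec$in_channels != 1L) {
    stop("baseline cnn1d must have in_channels = 1, got ", spec$in_channels)
  }
  head <- make_classifier(spec)
  if (spec$family == "lstm") head$build(spec$segment_len)
  if (spec$family == "transformer") {
    head$build(spec$segment_len, as.integer(ceiling(D / spec$segment_len)))
  }
  params <- if (!is.null(head$env)) head$env$params else head$params
  model <- list(spec = spec, D = D, params = params, states = head$states,
                kind = "baseline", head = head)
  model$forward <- function(X, mode = "eval") {
    X <- as.matrix(X)
    if (ncol(X) != D) stop("expected D = ", D, " columns, got ", ncol(X))
    if (spec$family == "cnn1d") {
      head$forward(array(X, c(nrow(X), 1L, D)), mode)
    } else {
      head$forward(segment_sequence(X, spec$segment_len), mode)
    }
  }
  model
}

#' Compose the MSMCE module with a classification head end-to-end
#'
#' The head consumes the `[B, 1+C, d]` module output: cnn1d as `1+C` input
#' channels; the sequence families treat the channels as the sequence axis
#' (length `1+C`) with feature length `d`. One loss trains all parameters
#' jointly.
#'
#' @param msmce an [msmce_init()] module or an [msmce_config()].
#' @param spec a [classifier_spec()]; for cnn1d, `in_channels` must equal
#'   `1 + C`.
#' @return a trainable model with `$forward(X [B x D], mode)`.
#' @export
compose <- function(msmce, spec) {
  if (inherits(msmce, "msmce_config")) msmce <- msmce_init(msmce)
  stopifnot(inherits(msmce, "msmce_module"))
  cfg <- msmce$cfg
  if (spec$family == "cnn1d" && spec$in_channels != 1L + cfg$C) {
    stop("configuration error: cnn1d in_channels (", spec$in_channels,
         ") must equal 1 + C (", 1L + cfg$C, ")")
  }
  head <- make_classifier(spec)
  if (spec$family == "lstm") head$build(cfg$d)
  if (spec$family == "transformer") head$build(cfg$d, 1L + cfg$C)
  head_params <- if (!is.null(head$env)) head$env$params else head$params
  params <- c(prefix_names(msmce$params, "msmce_"),
              prefix_names(head_params, "head_"))
  states <- c(prefix_names(msmce$states, "msmce_"),
              prefix_names(head$states, "head_"))
  model <- list(spec = spec, msmce = msmce, head = head, cfg = cfg,
                D = cfg$D, params = params, states = states, kind = "msmce")
  model$forward <- function(X, mode = "eval") {
    O <- msmce_forward(X, msmce, mode)
    head$forward(O, mode)
  }
  model
}
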
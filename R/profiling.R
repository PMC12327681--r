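# Analytic computational-cost accounting.
#
# MACs (multiply-accumulate operations) for a single-sample forward pass
# are counted from closed forms per layer kind; following the convention
# of the usual profiler tools, results can be read as "FLOPs" with one
# multiply-add = 1 unit, and normalizations/activations count as zero.
# Parameter counts are exact (taken from the live parameter tensors).

mac_linear <- function(n_in, n_out) n_in * n_out
mac_conv1d <- function(L_out, C_out, C_in, k) L_out * C_out * C_in * k
mac_lstm <- function(L, Fdim, H) L * 4 * (Fdim * H + H * H)
mac_attention_layer <- function(Lp, dm, ff) {
  4 * Lp * dm * dm +        # Q, K, V and output projections
    2 * Lp * Lp * dm +      # attention scores and weighted sum (all heads)
    2 * Lp * dm * ff        # position-wise feed-forward
}

# Layer table (kind, macs, activation scalars) for one sample. `shape` is
# the per-sample input shape the model consumes.
model_layer_table <- function(model, input_shape = NULL) {
  rows <- list()
  add <- function(name, kind, macs, act) {
    rows[[length(rows) + 1L]] <<- data.frame(layer = name, kind = kind,
                                             macs = macs, act = act)
  }
  if (inherits(model, "msmce_module")) {
    cfg <- model$cfg
    add("encoder_fc1", "linear", mac_linear(cfg$D, cfg$hidden), cfg$hidden)
    add("encoder_ln", "layernorm", 0, cfg$hidden)
    add("encoder_fc2", "linear", mac_linear(cfg$hidden, cfg$d), cfg$d)
    add("conv1", "conv1d", mac_conv1d(cfg$d, cfg$C_mid, 1L, cfg$kernel),
        cfg$C_mid * cfg$d)
    add("bn", "batchnorm", 0, cfg$C_mid * cfg$d)
    add("conv2", "conv1d", mac_conv1d(cfg$d, cfg$C, cfg$C_mid, cfg$kernel),
        cfg$C * cfg$d)
    add("concat", "concat", 0, (1L + cfg$C) * cfg$d)
    return(do.call(rbind, rows))
  }
  if (!is.null(model$kind) && model$kind == "msmce") {
    t1 <- model_layer_table(model$msmce)
    head_shape <- head_input_shape(model$spec, 1L + model$cfg$C, model$cfg$d)
    t2 <- model_layer_table(model$head, head_shape)
    t2$layer <- paste0("head_", t2$layer)
    return(rbind(t1, t2))
  }
  if (!is.null(model$kind) && model$kind == "baseline") {
    spec <- model$spec
    shape <- if (spec$family == "cnn1d") {
      c(1L, model$D)
    } else {
      c(as.integer(ceiling(model$D / spec$segment_len)), spec$segment_len)
    }
    return(model_layer_table(model$head, shape))
  }
  if (!is.null(model$spec)) {
    spec <- model$spec
    if (is.null(input_shape)) {
      stop("input_shape required to profile a bare classification head")
    }
    if (spec$family == "cnn1d") {
      L <- input_shape[2L]
      w <- spec$width
      add("stem", "conv1d", mac_conv1d(L, w, input_shape[1L], 3L), w * L)
      add("stem_bn", "batchnorm", 0, w * L)
      for (i in seq_len(spec$depth)) {
        add(paste0("res", i, "_conv1"), "conv1d", mac_conv1d(L, w, w, 3L), w * L)
        add(paste0("res", i, "_bn1"), "batchnorm", 0, w * L)
        add(paste0("res", i, "_conv2"), "conv1d", mac_conv1d(L, w, w, 3L), w * L)
        add(paste0("res", i, "_bn2"), "batchnorm", 0, w * L)
      }
      add("gap", "pool", 0, w)
      add("head", "linear", mac_linear(w, spec$n_classes), spec$n_classes)
    } else if (spec$family == "lstm") {
      L <- input_shape[1L]; Fdim <- input_shape[2L]
      add("lstm", "lstm", mac_lstm(L, Fdim, spec$hidden), L * spec$hidden)
      add("head", "linear", mac_linear(spec$hidden, spec$n_classes),
          spec$n_classes)
    } else if (spec$family == "transformer") {
      L <- input_shape[1L]; Fdim <- input_shape[2L]
      Lp <- L + 1L
      dm <- spec$d_model
      add("embed", "linear", L * mac_linear(Fdim, dm), Lp * dm)
      for (l in seq_len(spec$n_layers)) {
        add(paste0("layer", l), "attention",
            mac_attention_layer(Lp, dm, dm * spec$ff_mult),
            Lp * dm * (3L + spec$ff_mult))
      }
      add("final_ln", "layernorm", 0, Lp * dm)
      add("head", "linear", mac_linear(dm, spec$n_classes), spec$n_classes)
    } else {
      stop("unsupported layer family for profiling: ", spec$family)
    }
    return(do.call(rbind, rows))
  }
  stop("unsupported model object for profiling: ",
       paste(class(model), collapse = "/"))
}

head_input_shape <- function(spec, channels, len) {
  if (spec$family == "cnn1d") c(channels, len) else c(channels, len)
}

#' Count single-sample forward MACs of a model
#'
#' @param model an [msmce_init()] module, a [baseline_model()], a
#'   [compose()]d model, or a bare head (then give `input_shape`).
#' @param input_shape per-sample input shape for bare heads: `c(channels,
#'   length)` for cnn1d, `c(seq, feat)` for sequence families.
#' @return total multiply-accumulate count (numeric, exact integer value).
#' @export
count_macs <- function(model, input_shape = NULL) {
  sum(model_layer_table(model, input_shape)$macs)
}

#' Count learnable parameters of a model
#'
#' Exact count of scalars in the live parameter tensors; parameters with
#' `frozen = TRUE` are excluded.
#'
#' @param model any model with `$params` (a list of `ad_param` nodes).
#' @return total learnable-scalar count.
#' @export
count_params <- function(model) {
  params <- if (!is.null(model$params)) {
    model$params
  } else if (!is.null(model$env)) {
    model$env$params
  } else {
    stop("model has no parameters to count")
  }
  if (is.null(params)) stop("model parameters not yet materialized; call $build()")
  sum(vapply(params, function(p) {
    if (isTRUE(p$frozen)) 0L else length(p$value)
  }, 1L))
}

#' Estimate total model size in MB
#'
#' `4 bytes x (2 x params + batch x activations)`: parameters plus
#' same-sized gradients plus forward activations at the given batch size.
#' This is a closed-form estimate, not a measurement.
#'
#' @param model a profileable model.
#' @param batch_size batch size for the activation term.
#' @param input_shape as in [count_macs()].
#' @return estimated size in MB.
#' @export
est_size_mb <- function(model, batch_size = 64L, input_shape = NULL) {
  act <- sum(model_layer_table(model, input_shape)$act)
  p <- count_params(model)
  4 * (2 * p + batch_size * act) / 2^20
}

#' Side-by-side profile of a baseline and an MSMCE-composed model
#'
#' @param baseline,msmce two profileable models.
#' @param input_shape passed through for bare heads.
#' @param batch_size batch size for the size estimate.
#' @return data.frame with rows `baseline`, `msmce`, `ratio`
#'   (msmce/baseline) and columns `macs`, `params`, `est_size_mb`.
#' @export
profile_pair <- function(baseline, msmce, input_shape = NULL,
                         batch_size = 64L) {
  prof <- function(m) c(macs = count_macs(m, input_shape),
                        params = count_params(m),
                        est_size_mb = est_size_mb(m, batch_size, input_shape))
  b <- prof(baseline)
  m <- prof(msmce)
  out <- rbind(baseline = b, msmce = m, ratio = m / b)
  as.data.frame(out)
}
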
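# Reverse-mode automatic differentiation on dense arrays.
#
# Every differentiable quantity is an `ad_node`: an environment holding a
# numeric array (`value`), an accumulated gradient (`grad`), its `parents`
# and a `backward` closure that maps the node's gradient to a list of
# parent gradients (NULL entries for non-differentiable parents).
# Graphs are rebuilt on every forward pass; parameter nodes persist across
# passes so an optimizer can update `value` in place and read `grad` after
# `ad_backward()`.

#' Create a computation-graph node
#'
#' @param value numeric array, matrix or vector.
#' @param parents list of parent `ad_node`s.
#' @param backward function(grad) returning a list of gradients aligned
#'   with `parents` (NULL for parents that receive no gradient).
#' @return an object of class `ad_node`.
#' @keywords internal
ad_node <- function(value, parents = list(), backward = NULL) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- NULL
  e$parents <- parents
  e$backward <- backward
  e$is_param <- FALSE
  e$frozen <- FALSE
  e$.tok <- 0L
  class(e) <- "ad_node"
  e
}

#' Create a learnable parameter node
#' @param value initial numeric array.
#' @return an `ad_node` flagged as a parameter.
#' @keywords internal
ad_param <- function(value) {
  n <- ad_node(value)
  n$is_param <- TRUE
  n
}

# Coerce plain numerics into constant nodes so forward functions accept both.
as_ad <- function(x) if (inherits(x, "ad_node")) x else ad_node(x)

.ad_counter <- local({
  i <- 0L
  function() {
    i <<- i + 1L
    i
  }
})

# Topological order (parents before children), iterative to avoid deep
# recursion on long sequence graphs.
ad_toposort <- function(root) {
  tok <- .ad_counter()
  order <- vector("list", 64L)
  n_ord <- 0L
  stack <- vector("list", 64L)
  stack[[1L]] <- list(n = root, expanded = FALSE)
  top <- 1L
  while (top > 0L) {
    fr <- stack[[top]]
    stack[top] <- list(NULL)
    top <- top - 1L
    if (fr$expanded) {
      n_ord <- n_ord + 1L
      if (n_ord > length(order)) order <- c(order, vector("list", length(order)))
      order[[n_ord]] <- fr$n
      next
    }
    n <- fr$n
    if (n$.tok == tok) next
    n$.tok <- tok
    top <- top + 1L
    if (top > length(stack)) stack <- c(stack, vector("list", length(stack)))
    stack[[top]] <- list(n = n, expanded = TRUE)
    for (p in n$parents) {
      if (p$.tok != tok) {
        top <- top + 1L
        if (top > length(stack)) stack <- c(stack, vector("list", length(stack)))
        stack[[top]] <- list(n = p, expanded = FALSE)
      }
    }
  }
  order[seq_len(n_ord)]
}

#' Backpropagate gradients from a scalar root node
#'
#' Clears stale gradients on the whole graph, seeds the root with 1 and
#' accumulates gradients into every reachable node (parameters included).
#' @param root scalar `ad_node` (typically a loss).
#' @keywords internal
ad_backward <- function(root) {
  if (length(root$value) != 1L) {
    stop("ad_backward() expects a scalar root node, got length ", length(root$value))
  }
  order <- ad_toposort(root)
  for (n in order) n$grad <- NULL
  root$grad <- 1
  for (i in rev(seq_along(order))) {
    n <- order[[i]]
    if (is.null(n$backward) || is.null(n$grad)) next
    gs <- n$backward(n$grad)
    ps <- n$parents
    for (j in seq_along(ps)) {
      g <- gs[[j]]
      if (is.null(g)) next
      p <- ps[[j]]
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
  }
  invisible(root)
}

# ---- elementary operations -------------------------------------------------

ad_matmul <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  av <- a$value; bv <- b$value
  ad_node(av %*% bv, list(a, b), function(g) {
    list(g %*% t(bv), crossprod(av, g))
  })
}

# Add a bias vector to every row of a matrix.
ad_add_rowvec <- function(x, b) {
  x <- as_ad(x); b <- as_ad(b)
  bv <- b$value
  ad_node(sweep(x$value, 2L, bv, "+"), list(x, b), function(g) {
    list(g, colSums(g))
  })
}

ad_add <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  ad_node(a$value + b$value, list(a, b), function(g) list(g, g))
}

ad_sub <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  ad_node(a$value - b$value, list(a, b), function(g) list(g, -g))
}

ad_mul <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  av <- a$value; bv <- b$value
  ad_node(av * bv, list(a, b), function(g) list(g * bv, g * av))
}

ad_scale <- function(x, s) {
  x <- as_ad(x)
  ad_node(x$value * s, list(x), function(g) list(g * s))
}

ad_relu <- function(x) {
  x <- as_ad(x)
  v <- x$value
  out <- v
  out[out < 0] <- 0
  ad_node(out, list(x), function(g) {
    gi <- g
    gi[v <= 0] <- 0
    list(gi)
  })
}

ad_sigmoid <- function(x) {
  x <- as_ad(x)
  s <- 1 / (1 + exp(-x$value))
  ad_node(s, list(x), function(g) list(g * s * (1 - s)))
}

ad_tanh <- function(x) {
  x <- as_ad(x)
  th <- tanh(x$value)
  ad_node(th, list(x), function(g) list(g * (1 - th^2)))
}

ad_sum <- function(x) {
  x <- as_ad(x)
  dm <- dim(x$value)
  ad_node(sum(x$value), list(x), function(g) {
    gr <- array(g, dim = if (is.null(dm)) length(x$value) else dm)
    list(gr)
  })
}

ad_mean <- function(x) ad_scale(ad_sum(x), 1 / length(as_ad(x)$value))

# ---- shape manipulation ----------------------------------------------------

ad_reshape <- function(x, dm) {
  x <- as_ad(x)
  old <- dim(x$value)
  v <- x$value
  dim(v) <- dm
  ad_node(v, list(x), function(g) {
    dim(g) <- old
    list(g)
  })
}

ad_aperm <- function(x, perm) {
  x <- as_ad(x)
  inv <- order(perm)
  ad_node(aperm(x$value, perm), list(x), function(g) list(aperm(g, inv)))
}

# Select rows of a matrix; gradient scatters back.
ad_rows <- function(x, idx) {
  x <- as_ad(x)
  dm <- dim(x$value)
  ad_node(x$value[idx, , drop = FALSE], list(x), function(g) {
    gr <- matrix(0, dm[1L], dm[2L])
    gr[idx, ] <- gr[idx, ] + g
    list(gr)
  })
}

ad_cols <- function(x, idx) {
  x <- as_ad(x)
  dm <- dim(x$value)
  ad_node(x$value[, idx, drop = FALSE], list(x), function(g) {
    gr <- matrix(0, dm[1L], dm[2L])
    gr[, idx] <- gr[, idx] + g
    list(gr)
  })
}

ad_rbind <- function(nodes) {
  nodes <- lapply(nodes, as_ad)
  vals <- lapply(nodes, function(n) n$value)
  nr <- vapply(vals, nrow, 1L)
  ends <- cumsum(nr)
  starts <- ends - nr + 1L
  ad_node(do.call(rbind, vals), nodes, function(g) {
    lapply(seq_along(nodes), function(i) g[starts[i]:ends[i], , drop = FALSE])
  })
}

ad_t <- function(x) {
  x <- as_ad(x)
  ad_node(t(x$value), list(x), function(g) list(t(g)))
}

# Concatenate two [B, C, L] tensors along the channel axis.
ad_concat_channels <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  da <- dim(a$value); db <- dim(b$value)
  stopifnot(length(da) == 3L, length(db) == 3L, da[1L] == db[1L], da[3L] == db[3L])
  B <- da[1L]; L <- da[3L]
  out <- array(0, c(B, da[2L] + db[2L], L))
  out[, seq_len(da[2L]), ] <- a$value
  out[, da[2L] + seq_len(db[2L]), ] <- b$value
  ad_node(out, list(a, b), function(g) {
    list(
      array(g[, seq_len(da[2L]), , drop = FALSE], da),
      array(g[, da[2L] + seq_len(db[2L]), , drop = FALSE], db)
    )
  })
}

# Global average pooling over the length axis: [B, C, L] -> [B, C].
ad_gap <- function(x) {
  x <- as_ad(x)
  dm <- dim(x$value)
  B <- dm[1L]; C <- dm[2L]; L <- dm[3L]
  v <- apply(x$value, c(1L, 2L), mean)
  dim(v) <- c(B, C)
  ad_node(v, list(x), function(g) {
    gr <- array(rep(as.vector(g) / L, L), c(B, C, L))
    list(gr)
  })
}

# ---- normalization, dropout ------------------------------------------------

# Layer normalization over the feature (column) axis of a [B, F] matrix,
# with learnable per-feature gain and shift.
ad_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  x <- as_ad(x); gamma <- as_ad(gamma); beta <- as_ad(beta)
  v <- x$value
  mu <- rowMeans(v)
  xc <- v - mu
  va <- rowMeans(xc^2)
  sd_inv <- 1 / sqrt(va + eps)
  xhat <- xc * sd_inv
  out <- sweep(sweep(xhat, 2L, gamma$value, "*"), 2L, beta$value, "+")
  ad_node(out, list(x, gamma, beta), function(g) {
    gg <- sweep(g, 2L, gamma$value, "*")
    m1 <- rowMeans(gg)
    m2 <- rowMeans(gg * xhat)
    dx <- (gg - m1 - xhat * m2) * sd_inv
    list(dx, colSums(g * xhat), colSums(g))
  })
}

# Inverted dropout: active only in train mode, scales retained units by
# 1/(1-p) so eval mode is the identity.
ad_dropout <- function(x, p, mode) {
  x <- as_ad(x)
  if (mode != "train" || p <= 0) return(x)
  keep <- (stats::runif(length(x$value)) >= p) / (1 - p)
  dim(keep) <- dim(x$value)
  ad_node(x$value * keep, list(x), function(g) list(g * keep))
}

# Batch normalization over the channel axis of a [B, C, L] tensor.
# `state` is an environment holding running_mean / running_var, updated in
# train mode (unbiased variance, momentum 0.1, matching common framework
# semantics); eval mode normalizes with the running statistics.
ad_batchnorm <- function(x, gamma, beta, state, mode, momentum = 0.1, eps = 1e-5) {
  x <- as_ad(x); gamma <- as_ad(gamma); beta <- as_ad(beta)
  v <- x$value
  dm <- dim(v)
  B <- dm[1L]; C <- dm[2L]; L <- dm[3L]
  n <- B * L
  if (mode == "train") {
    if (B < 2L) {
      stop("batch normalization in train mode needs batch size >= 2 ",
           "(batch variance is undefined for a single sample)")
    }
    mu <- apply(v, 2L, mean)
    xc <- sweep(v, 2L, mu, "-")
    va <- apply(xc^2, 2L, mean)                      # biased, used to normalize
    state$running_mean <- (1 - momentum) * state$running_mean + momentum * mu
    state$running_var <- (1 - momentum) * state$running_var +
      momentum * va * n / (n - 1)                    # unbiased for running stats
    sd_inv <- 1 / sqrt(va + eps)
    xhat <- sweep(xc, 2L, sd_inv, "*")
    out <- sweep(sweep(xhat, 2L, gamma$value, "*"), 2L, beta$value, "+")
    ad_node(out, list(x, gamma, beta), function(g) {
      gg <- sweep(g, 2L, gamma$value, "*")
      m1 <- apply(gg, 2L, mean)
      m2 <- apply(gg * xhat, 2L, mean)
      dx <- sweep(sweep(gg, 2L, m1, "-") - sweep(xhat, 2L, m2, "*"),
                  2L, sd_inv, "*")
      list(dx, apply(g * xhat, 2L, sum), apply(g, 2L, sum))
    })
  } else {
    sd_inv <- 1 / sqrt(state$running_var + eps)
    xhat <- sweep(sweep(v, 2L, state$running_mean, "-"), 2L, sd_inv, "*")
    out <- sweep(sweep(xhat, 2L, gamma$value, "*"), 2L, beta$value, "+")
    ad_node(out, list(x, gamma, beta), function(g) {
      dx <- sweep(sweep(g, 2L, gamma$value, "*"), 2L, sd_inv, "*")
      list(dx, apply(g * xhat, 2L, sum), apply(g, 2L, sum))
    })
  }
}

# ---- convolution -----------------------------------------------------------

# 1-D convolution with stride 1 and symmetric zero padding (kernel-1)/2 so
# the length axis is preserved. x: [B, Cin, L]; kernel: [Cout, Cin, k];
# bias: [Cout]. Implemented as k accumulated GEMMs (one per tap).
ad_conv1d <- function(x, kernel, bias, pad = NULL) {
  x <- as_ad(x); kernel <- as_ad(kernel); bias <- as_ad(bias)
  v <- x$value
  dm <- dim(v)
  B <- dm[1L]; Cin <- dm[2L]; L <- dm[3L]
  kd <- dim(kernel$value)
  Cout <- kd[1L]; k <- kd[3L]
  if (kd[2L] != Cin) {
    stop("conv1d channel mismatch: input has ", Cin, " channels, kernel expects ", kd[2L])
  }
  if (is.null(pad)) pad <- (k - 1L) %/% 2L
  Lp <- L + 2L * pad
  xp <- array(0, c(B, Cin, Lp))
  xp[, , pad + seq_len(L)] <- v
  # per-tap input matrices, kept for the backward pass
  mats <- vector("list", k)
  out_mat <- matrix(0, B * L, Cout)
  for (j in seq_len(k)) {
    sl <- aperm(array(xp[, , j:(j + L - 1L), drop = FALSE], c(B, Cin, L)), c(1L, 3L, 2L))
    dim(sl) <- c(B * L, Cin)
    mats[[j]] <- sl
    kj <- matrix(kernel$value[, , j], nrow = Cout, ncol = Cin)
    out_mat <- out_mat + sl %*% t(kj)
  }
  out_mat <- sweep(out_mat, 2L, bias$value, "+")
  out <- aperm(array(out_mat, c(B, L, Cout)), c(1L, 3L, 2L))
  ad_node(out, list(x, kernel, bias), function(g) {
    g_mat <- aperm(g, c(1L, 3L, 2L))
    dim(g_mat) <- c(B * L, Cout)
    dk <- array(0, kd)
    dxp <- array(0, c(B, Cin, Lp))
    for (j in seq_len(k)) {
      dk[, , j] <- crossprod(g_mat, mats[[j]])
      kj <- matrix(kernel$value[, , j], nrow = Cout, ncol = Cin)
      dsl <- g_mat %*% kj
      dim(dsl) <- c(B, L, Cin)
      dxp[, , j:(j + L - 1L)] <- dxp[, , j:(j + L - 1L), drop = FALSE] +
        aperm(dsl, c(1L, 3L, 2L))
    }
    dx <- array(dxp[, , pad + seq_len(L), drop = FALSE], dm)
    list(dx, dk, colSums(g_mat))
  })
}

# ---- softmax / losses ------------------------------------------------------

ad_softmax_rows <- function(x) {
  x <- as_ad(x)
  v <- x$value
  v <- v - apply(v, 1L, max)
  e <- exp(v)
  p <- e / rowSums(e)
  ad_node(p, list(x), function(g) {
    list(p * (g - rowSums(g * p)))
  })
}

#' Class-weighted cross-entropy loss
#'
#' Mean negative log-likelihood over a batch with per-class weights; the
#' batch mean is weighted (divide by the summed weights of the realized
#' labels), matching the convention of mainstream deep-learning frameworks.
#'
#' @param logits `ad_node` of shape `[B, K]`.
#' @param y integer class labels in `1..K`.
#' @param weights per-class positive weights, length `K` (default all 1).
#' @return scalar `ad_node`.
#' @keywords internal
ad_cross_entropy <- function(logits, y, weights = NULL) {
  logits <- as_ad(logits)
  v <- logits$value
  B <- nrow(v); K <- ncol(v)
  if (is.null(weights)) weights <- rep(1, K)
  stopifnot(length(y) == B, all(y >= 1L & y <= K))
  m <- apply(v, 1L, max)
  z <- v - m
  lse <- log(rowSums(exp(z)))
  logp <- z - lse
  wy <- weights[y]
  wsum <- sum(wy)
  picked <- logp[cbind(seq_len(B), y)]
  loss <- -sum(wy * picked) / wsum
  p <- exp(logp)
  ad_node(loss, list(logits), function(g) {
    onehot <- matrix(0, B, K)
    onehot[cbind(seq_len(B), y)] <- 1
    list(g * (p - onehot) * wy / wsum)
  })
}

# Numerical gradient of f (returning a scalar) w.r.t. the values of `node`,
# by central finite differences. Used as the independent oracle in tests.
ad_finite_diff <- function(f, node, eps = 1e-5) {
  v0 <- node$value
  g <- array(0, dim = if (is.null(dim(v0))) length(v0) else dim(v0))
  for (i in seq_along(v0)) {
    node$value[i] <- v0[i] + eps
    fp <- f()
    node$value[i] <- v0[i] - eps
    fm <- f()
    node$value[i] <- v0[i]
    g[i] <- (fp - fm) / (2 * eps)
  }
  g
}
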
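test_that("segment_sequence chunks row-major with zero padding and is invertible", {
  X <- matrix(1:12, 2, 6, byrow = TRUE)
  s <- segment_sequence(X, 2)
  expect_identical(dim(s), c(2L, 3L, 2L))
  expect_equal(s[1, 1, ], c(1, 2))
  expect_equal(s[1, 3, ], c(5, 6))
  # D = 5: last chunk zero-padded
  X5 <- matrix(1:10, 2, 5, byrow = TRUE)
  s5 <- segment_sequence(X5, 2)
  expect_identical(dim(s5), c(2L, 3L, 2L))
  expect_equal(s5[1, 3, ], c(5, 0))
  expect_error(segment_sequence(X, 0), "segment_len")
  # round trip for random matrices and segment lengths
  set.seed(8)
  for (i in 1:10) {
    D <- sample(3:40, 1)
    sl <- sample(1:9, 1)
    X <- matrix(rnorm(3 * D), 3, D)
    s <- segment_sequence(X, sl)
    flat <- t(apply(s, 1, function(m) as.vector(t(m))))
    expect_equal(flat[, seq_len(D), drop = FALSE], X)
    if (ncol(flat) > D) expect_true(all(flat[, -seq_len(D)] == 0))
  }
})

test_that("all three families produce [B, n_classes] logits", {
  set.seed(9)
  B <- 3L
  x_cnn <- array(rnorm(B * 2 * 12), c(B, 2, 12))
  x_seq <- array(rnorm(B * 4 * 6), c(B, 4, 6))
  cnn <- make_classifier(classifier_spec("cnn1d", n_classes = 3,
                                         in_channels = 2, width = 4, depth = 1))
  expect_identical(dim(cnn$forward(x_cnn, "eval")$value), c(B, 3L))
  lstm <- make_classifier(classifier_spec("lstm", n_classes = 4, hidden = 5))
  expect_identical(dim(lstm$forward(x_seq, "eval")$value), c(B, 4L))
  trf <- make_classifier(classifier_spec("transformer", n_classes = 2,
                                         d_model = 8, heads = 2, n_layers = 1))
  expect_identical(dim(trf$forward(x_seq, "eval")$value), c(B, 2L))
  expect_error(cnn$forward(x_seq, "eval"), "expects input")
})

test_that("transformer prepends exactly one CLS position", {
  # position embedding is sized L+1; a mismatched sequence length errors
  trf <- make_classifier(classifier_spec("transformer", n_classes = 2,
                                         d_model = 8, heads = 2, n_layers = 1))
  trf$build(6, 4)
  expect_identical(dim(trf$env$params$pos$value), c(5L, 8L))
  expect_error(trf$forward(array(0, c(2, 7, 6)), "eval"), "seq len")
})

test_that("compose wires MSMCE output into each family and checks channels", {
  set.seed(10)
  cfg <- tiny_cfg(D = 10L)       # C = 3 -> 4 channels
  X <- matrix(rnorm(3 * 10), 3, 10)
  # cnn1d channel wiring is validated at construction
  expect_error(compose(cfg, classifier_spec("cnn1d", n_classes = 2,
                                            in_channels = 3)),
               "configuration error")
  m <- compose(cfg, classifier_spec("cnn1d", n_classes = 2, in_channels = 4,
                                    width = 4, depth = 1))
  expect_identical(dim(m$forward(X, "eval")$value), c(3L, 2L))
  expect_identical(dim(m$params$head_stem_K$value), c(4L, 4L, 3L))
  # sequence families: seq len 1+C, feature length d
  mt <- compose(cfg, classifier_spec("transformer", n_classes = 2,
                                     d_model = 8, heads = 2, n_layers = 1))
  expect_identical(dim(mt$params$head_pos$value), c(5L, 8L))  # (1+C)+CLS
  expect_identical(nrow(mt$params$head_embed_W$value), 5L)    # feature = d
  expect_identical(dim(mt$forward(X, "eval")$value), c(3L, 2L))
  ml <- compose(cfg, classifier_spec("lstm", n_classes = 2, hidden = 6))
  expect_identical(dim(ml$forward(X, "eval")$value), c(3L, 2L))
})

test_that("with a frozen MSMCE, compose equals classifier(msmce_forward(X))", {
  set.seed(11)
  cfg <- tiny_cfg(D = 10L)
  mod <- msmce_init(cfg)
  m <- compose(mod, classifier_spec("cnn1d", n_classes = 2, in_channels = 4,
                                    width = 4, depth = 1))
  X <- matrix(rnorm(2 * 10), 2, 10)
  direct <- m$head$forward(msmce_forward(X, mod, "eval"), "eval")$value
  expect_identical(m$forward(X, "eval")$value, direct)
})

test_that("the composed loss backpropagates into the encoder weights", {
  set.seed(12)
  cfg <- tiny_cfg(D = 10L)
  for (fam in c("cnn1d", "lstm", "transformer")) {
    spec <- switch(fam,
      cnn1d = classifier_spec("cnn1d", n_classes = 2, in_channels = 4,
                              width = 4, depth = 1),
      lstm = classifier_spec("lstm", n_classes = 2, hidden = 5),
      transformer = classifier_spec("transformer", n_classes = 2, d_model = 8,
                                    heads = 2, n_layers = 1, dropout_p = 0))
    m <- compose(cfg, spec)
    X <- matrix(rnorm(4 * 10), 4, 10)
    loss <- msmce:::ad_cross_entropy(m$forward(X, "train"), c(1L, 2L, 1L, 2L))
    msmce:::ad_backward(loss)
    g <- m$params$msmce_W1$grad
    expect_false(is.null(g))
    expect_gt(max(abs(g)), 0)
  }
})

test_that("composed gradient on W1 matches finite differences (tiny config)", {
  set.seed(13)
  cfg <- tiny_cfg(D = 8L)
  mod <- msmce_init(cfg)
  spec <- classifier_spec("cnn1d", n_classes = 2, in_channels = 4, width = 3,
                          depth = 1, dropout_p = 0)
  m <- compose(mod, spec)
  X <- matrix(rnorm(3 * 8), 3, 8)
  y <- c(1L, 2L, 1L)
  fresh <- function() {
    for (st in m$states) {
      st$running_mean <- st$running_mean * 0
      st$running_var <- st$running_var * 0 + 1
    }
    msmce:::ad_cross_entropy(m$forward(X, "train"), y)
  }
  loss <- fresh()
  msmce:::ad_backward(loss)
  fd <- msmce:::ad_finite_diff(function() fresh()$value, m$params$msmce_W1)
  expect_grad_matches(m$params$msmce_W1, fd, tol = 1e-4)
})
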
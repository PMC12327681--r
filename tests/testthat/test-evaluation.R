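test_that("confusion_matrix counts (true, predicted) pairs", {
  cm <- confusion_matrix(c(1, 2, 2), c(1, 2, 2), K = 2)
  expect_equal(cm, matrix(c(1L, 0L, 0L, 2L), 2, 2))
  # mode collapse: every prediction in column 1
  cmc <- confusion_matrix(rep(1:2, each = 10), rep(1, 20), K = 2)
  expect_equal(cmc[, 1], c(10L, 10L))
  expect_true(all(cmc[, 2] == 0L))
  expect_error(confusion_matrix(c(1, 3), c(1, 1), K = 2), "out of range")
  # brute-force tally oracle on random label vectors
  set.seed(30)
  for (i in 1:20) {
    K <- sample(2:5, 1)
    n <- sample(10:60, 1)
    yt <- sample.int(K, n, replace = TRUE)
    yp <- sample.int(K, n, replace = TRUE)
    cm <- confusion_matrix(yt, yp, K = K)
    expect_equal(sum(cm), n)
    oracle <- matrix(0L, K, K)
    for (j in seq_len(n)) oracle[yt[j], yp[j]] <- oracle[yt[j], yp[j]] + 1L
    expect_equal(cm, oracle)
  }
})

test_that("macro metrics: perfect, collapsed and random cases", {
  mm <- macro_metrics(matrix(c(5L, 0L, 0L, 5L), 2, 2))
  expect_equal(mm$accuracy, 1)
  expect_equal(mm$macro_f1, 1)
  # balanced binary collapse: macro F1 = (2*10/30 + 0)/2 = 0.3333
  col <- macro_metrics(rbind(c(10L, 0L), c(10L, 0L)))
  expect_equal(col$macro_f1, 1 / 3, tolerance = 1e-12)
  expect_equal(round(col$macro_f1, 4), 0.3333)
  expect_equal(col$accuracy, 0.5)
  expect_equal(col$macro_accuracy, 0.5)
  expect_error(macro_metrics(matrix(0L, 2, 2)), "empty")
  # independent per-class computation on random 3-class matrices
  set.seed(31)
  for (i in 1:10) {
    cm <- matrix(rpois(9, 5), 3, 3)
    if (sum(cm) == 0) next
    mm <- macro_metrics(cm)
    prec <- rec <- f1 <- numeric(3)
    for (k in 1:3) {
      tp <- cm[k, k]; fp <- sum(cm[, k]) - tp; fn <- sum(cm[k, ]) - tp
      prec[k] <- if (tp + fp > 0) tp / (tp + fp) else 0
      rec[k] <- if (tp + fn > 0) tp / (tp + fn) else 0
      f1[k] <- if (prec[k] + rec[k] > 0) 2 * prec[k] * rec[k] / (prec[k] + rec[k]) else 0
    }
    expect_equal(mm$macro_f1, mean(f1))
    expect_equal(mm$macro_precision, mean(prec))
    expect_equal(mm$macro_accuracy, mean(rec))
    expect_equal(mm$accuracy, sum(diag(cm)) / sum(cm))
  }
  # macro-F1 is invariant to class relabeling
  cm <- matrix(c(8L, 2L, 1L, 5L, 9L, 0L, 3L, 1L, 7L), 3, 3)
  perm <- c(3L, 1L, 2L)
  expect_equal(macro_metrics(cm[perm, perm])$macro_f1, macro_metrics(cm)$macro_f1)
})

test_that("exact Wilcoxon: floor case, symmetry, ties, reference agreement", {
  # 6 uniformly-signed distinct differences: p = 2/2^6
  w <- wilcoxon_exact_paired(c(2, 3, 4, 5, 6, 7), rep(1, 6))
  expect_equal(w$p_value, 0.03125)
  expect_equal(round(w$p_value, 2), 0.03)
  # symmetry and the all-zero guard
  a <- c(0.9, 0.8, 0.85, 0.95, 0.7, 0.75)
  b <- c(0.88, 0.82, 0.8, 0.9, 0.72, 0.8)
  expect_equal(wilcoxon_exact_paired(a, b)$p_value,
               wilcoxon_exact_paired(b, a)$p_value)
  expect_warning(wz <- wilcoxon_exact_paired(a, a), "zero")
  expect_equal(wz$p_value, 1)
  # smallest attainable two-sided p for k sign-consistent distinct pairs
  for (k in 2:8) {
    p <- wilcoxon_exact_paired(seq_len(k) + 1, rep(1, k))$p_value
    expect_equal(p, 2^(1 - k))
  }
  # agreement with the exact reference implementation (no ties, no zeros)
  set.seed(32)
  for (i in 1:100) {
    k <- 6
    x <- round(rnorm(k), 3)
    y <- round(rnorm(k), 3)
    d <- x - y
    if (any(d == 0) || anyDuplicated(abs(d[d != 0]))) next
    ref <- stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value
    expect_equal(wilcoxon_exact_paired(x, y)$p_value, ref, tolerance = 1e-12)
  }
  # ties get mid-ranks and the enumeration still sums to a valid p
  wt <- wilcoxon_exact_paired(c(2, 2, 3, 4, 5, 6), rep(1, 6))
  expect_true(wt$p_value > 0 && wt$p_value <= 1)
  expect_equal(wt$p_value, 0.03125)  # still all-positive: floor unchanged
})

test_that("bootstrap CI is seeded, ordered, and covers the mean reasonably", {
  v <- c(0.8, 0.9, 0.85, 0.95, 0.9, 0.88)
  ci <- bootstrap_ci(v, seed = 7)
  expect_identical(ci, bootstrap_ci(v, seed = 7))
  expect_lte(ci$lo, ci$mean)
  expect_gte(ci$hi, ci$mean)
  cc <- bootstrap_ci(rep(0.5, 5), seed = 1)
  expect_equal(cc$lo, 0.5)
  expect_equal(cc$hi, 0.5)
  # coverage on Gaussian fold scores: ~95% within simulation tolerance
  set.seed(33)
  hits <- 0L
  n_rep <- 300L
  for (i in seq_len(n_rep)) {
    x <- rnorm(20, 0.8, 0.05)
    ci <- bootstrap_ci(x, n_boot = 400, seed = i)
    if (ci$lo <= 0.8 && 0.8 <= ci$hi) hits <- hits + 1L
  }
  expect_gt(hits / n_rep, 0.95 - 0.05)
  expect_lt(hits / n_rep, 1)
})

test_that("relative improvement reproduces the printed reporting convention", {
  expect_equal(relative_improvement(0.9661, 0.9785), 1.28)
  expect_equal(relative_improvement(0.7848, 0.9933), 26.57)
  expect_equal(relative_improvement(0.5, 0.5), 0)
  expect_error(relative_improvement(0, 0.5), "baseline")
})

test_that("metrics_report aggregates fold metrics with CIs", {
  df <- data.frame(fold = 1:6, accuracy = c(0.9, 0.92, 0.88, 0.91, 0.9, 0.93),
                   macro_f1 = c(0.89, 0.91, 0.87, 0.9, 0.89, 0.92))
  rep <- metrics_report(df, cm = matrix(c(10L, 1L, 2L, 9L), 2, 2), seed = 2)
  expect_s3_class(rep, "metrics_report")
  expect_equal(rep$summary$accuracy$mean, mean(df$accuracy))
  expect_lte(rep$summary$accuracy$ci_lo, rep$summary$accuracy$mean)
  expect_output(print(rep), "accuracy")
})
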
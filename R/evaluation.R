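# Metrics and fold-wise statistical comparison.
#
# Includes the macro-averaged metric conventions used for multi-class MS
# classification reports, an exact (enumeration-based) paired Wilcoxon
# signed-rank test suited to k = 6 cross-validation folds, percentile
# bootstrap confidence intervals, and the relative-improvement convention
# used when comparing a model against its baseline.

#' Confusion matrix
#'
#' @param y_true,y_pred labels; either integers in `1..K` or values from
#'   `levels`.
#' @param K number of classes (inferred from `levels` if given).
#' @param levels optional class labels fixing row/column order.
#' @return integer matrix `[K x K]`; entry `(i, j)` counts true class `i`
#'   predicted as class `j`.
#' @export
confusion_matrix <- function(y_true, y_pred, K = NULL, levels = NULL) {
  if (!is.null(levels)) {
    y_true <- match(as.character(y_true), levels)
    y_pred <- match(as.character(y_pred), levels)
    K <- length(levels)
  }
  stopifnot(length(y_true) == length(y_pred), !is.null(K))
  y_true <- as.integer(y_true)
  y_pred <- as.integer(y_pred)
  if (anyNA(y_true) || anyNA(y_pred) ||
      any(y_true < 1L | y_true > K) || any(y_pred < 1L | y_pred > K)) {
    stop("labels out of range 1..", K)
  }
  cm <- matrix(0L, K, K)
  for (i in seq_along(y_true)) {
    cm[y_true[i], y_pred[i]] <- cm[y_true[i], y_pred[i]] + 1L
  }
  if (!is.null(levels)) dimnames(cm) <- list(true = levels, pred = levels)
  cm
}

#' Macro-averaged metrics from a confusion matrix
#'
#' Per-class precision, recall and F1 with unweighted ("macro") averages.
#' Classes with a zero denominator contribute 0 to the macro averages (a
#' collapsed binary classifier therefore scores macro-F1 1/2 * 2TP/(2TP+FP),
#' e.g. 0.3333 on a balanced set). Two accuracies are reported:
#' `accuracy` is the standard trace/total, and `macro_accuracy` is the
#' unweighted mean of per-class recall — the form some multi-class MS
#' reports print under the name "Accuracy".
#'
#' @param cm confusion matrix from [confusion_matrix()].
#' @return list with `accuracy`, `macro_accuracy`, `macro_f1`,
#'   `macro_precision`, `macro_recall` and per-class vectors `precision`,
#'   `recall`, `f1`.
#' @export
macro_metrics <- function(cm) {
  cm <- as.matrix(cm)
  if (length(cm) == 0L || sum(cm) == 0) stop("empty confusion matrix")
  K <- nrow(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  safe_div <- function(a, b) ifelse(b > 0, a / b, 0)
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  list(accuracy = sum(tp) / sum(cm),
       macro_accuracy = mean(recall),
       macro_precision = mean(precision),
       macro_recall = mean(recall),
       macro_f1 = mean(f1),
       precision = precision, recall = recall, f1 = f1)
}

#' Exact two-sided paired Wilcoxon signed-rank test
#'
#' Computes the exact two-sided p-value by full enumeration of all `2^k`
#' sign assignments of the absolute differences — no normal approximation,
#' which matters at cross-validation scale (k = 6, where the smallest
#' attainable two-sided p is `2^(1-k)` = 0.03125). Zero differences are
#' discarded before ranking; tied absolute differences receive mid-ranks.
#'
#' @param a,b paired score vectors of equal length.
#' @return list with `p_value`, `statistic` (the positive-rank sum W+ of
#'   the differences `a - b`) and `n_nonzero` (pairs retained after
#'   discarding zero differences).
#' @export
wilcoxon_exact_paired <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 1L)
  d <- a - b
  d <- d[d != 0]
  if (length(d) == 0L) {
    warning("all paired differences are zero; p = 1")
    return(list(p_value = 1, statistic = 0, n_nonzero = 0L))
  }
  k <- length(d)
  if (k > 20L) stop("exact enumeration is limited to 20 nonzero pairs (got ", k, ")")
  r <- rank(abs(d))                       # mid-ranks for ties
  w_obs <- sum(r[d > 0])
  # enumerate all sign assignments of the k ranks
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), k)))
  w_all <- as.vector(signs %*% r)
  p_ge <- mean(w_all >= w_obs)
  p_le <- mean(w_all <= w_obs)
  p <- min(1, 2 * min(p_ge, p_le))
  list(p_value = p, statistic = w_obs, n_nonzero = k)
}

#' Percentile bootstrap confidence interval for a mean
#'
#' @param values numeric vector (e.g. per-fold metrics), length >= 2.
#' @param n_boot bootstrap resamples (default 1000).
#' @param level confidence level (default 0.95).
#' @param seed integer seed.
#' @return list with `lo`, `hi`, `mean`.
#' @export
bootstrap_ci <- function(values, n_boot = 1000L, level = 0.95, seed = 1L) {
  stopifnot(length(values) >= 2L)
  rng <- local_rng(seed)
  on.exit(rng())
  n <- length(values)
  means <- vapply(seq_len(n_boot), function(i) {
    mean(values[sample.int(n, n, replace = TRUE)])
  }, 1.0)
  alpha <- (1 - level) / 2
  q <- stats::quantile(means, c(alpha, 1 - alpha), names = FALSE, type = 7)
  list(lo = q[1L], hi = q[2L], mean = mean(values))
}

#' Relative improvement in percent
#'
#' `100 * (improved - baseline) / baseline`, rounded to 2 decimals — the
#' convention used when reporting, e.g., an accuracy gain from 0.7848 to
#' 0.9933 as 26.57%.
#'
#' @param baseline,improved metric values; `baseline` must be positive.
#' @return percentage, rounded to 2 decimals.
#' @export
relative_improvement <- function(baseline, improved) {
  if (baseline <= 0) stop("baseline must be > 0")
  round(100 * (improved - baseline) / baseline, 2)
}

#' Full metrics report for a set of per-fold predictions
#'
#' @param fold_metrics data.frame with one row per fold and numeric metric
#'   columns (e.g. accuracy, macro_f1).
#' @param cm hold-out confusion matrix (optional).
#' @param n_boot,level,seed bootstrap settings for per-metric CIs.
#' @return an object of class `metrics_report`.
#' @export
metrics_report <- function(fold_metrics, cm = NULL, n_boot = 1000L,
                           level = 0.95, seed = 1L) {
  stopifnot(is.data.frame(fold_metrics))
  num_cols <- names(fold_metrics)[vapply(fold_metrics, is.numeric, TRUE)]
  num_cols <- setdiff(num_cols, "fold")
  summ <- lapply(stats::setNames(num_cols, num_cols), function(cn) {
    v <- fold_metrics[[cn]]
    ci <- bootstrap_ci(v, n_boot = n_boot, level = level, seed = seed)
    list(mean = mean(v), sd = stats::sd(v), ci_lo = ci$lo, ci_hi = ci$hi)
  })
  structure(list(fold_metrics = fold_metrics, summary = summ,
                 confusion = cm),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report> ", nrow(x$fold_metrics), " folds\n", sep = "")
  for (nm in names(x$summary)) {
    s <- x$summary[[nm]]
    cat(sprintf("  %-16s %.4f +/- %.4f  (95%% CI %.4f-%.4f)\n",
                nm, s$mean, s$sd, s$ci_lo, s$ci_hi))
  }
  if (!is.null(x$confusion)) {
    cat("  hold-out confusion matrix:\n")
    print(x$confusion)
  }
  invisible(x)
}
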
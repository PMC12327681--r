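# Data-processing workflow: raw runs -> feature matrix.
#
# Two instrument modes are supported. LC-MS runs are binned on the m/z axis
# and aggregated over 10-second retention-time windows; ambient (SpiderMass
# style) runs are TIC-filtered and binned scan by scan with no RT
# aggregation. Either way each retained row of the resulting matrix is one
# training instance.

#' Define an m/z bin grid
#'
#' Half-open bins `[mz_min + b*width, mz_min + (b+1)*width)` anchored at
#' the dataset's mass-range minimum. Peaks at or beyond `mz_max` fall
#' outside the grid and are dropped by [bin_spectrum()].
#'
#' @param mz_min,mz_max mass range in Da.
#' @param width bin width in Da (default 0.1).
#' @return an object of class `bin_grid`.
#' @export
bin_grid <- function(mz_min, mz_max, width = 0.1) {
  stopifnot(mz_max > mz_min, width > 0)
  n <- (mz_max - mz_min) / width
  # 1500/0.1 is not exactly 15000 in floating point; snap to the integer
  # when the ratio is within rounding error of one
  n_bins <- if (abs(n - round(n)) < 1e-6) as.integer(round(n)) else as.integer(ceiling(n))
  structure(list(mz_min = mz_min, mz_max = mz_max, width = width,
                 n_bins = n_bins),
            class = "bin_grid")
}

#' Total ion count of a spectrum
#'
#' @param spectrum an [ms_spectrum()].
#' @return sum of all intensities (0 for an empty scan).
#' @export
tic <- function(spectrum) {
  sum(spectrum$intensity)
}

#' Drop low-TIC spectra from a run
#'
#' Retains exactly the spectra whose TIC is at or above `threshold`
#' ("below" is strict), preserving order. Used for ambient-MS runs where
#' sub-threshold scans are acquisition noise.
#'
#' @param run an [ms_run()].
#' @param threshold TIC threshold (default `1e4`).
#' @return the filtered [ms_run()].
#' @export
filter_low_tic <- function(run, threshold = 1e4) {
  keep <- vapply(run$spectra, tic, 1.0) >= threshold
  if (!any(keep)) {
    stop("empty run after filtering: all ", length(keep), " spectra of '",
         run$file_id, "' have TIC below ", threshold)
  }
  run$spectra <- run$spectra[keep]
  run
}

#' Bin one spectrum onto an m/z grid
#'
#' Each peak's intensity is added to the half-open bin containing its m/z;
#' peaks outside `[mz_min, mz_max)` are dropped. The vector sum equals the
#' total in-range intensity.
#'
#' @param spectrum an [ms_spectrum()].
#' @param grid a [bin_grid()].
#' @return numeric vector of length `grid$n_bins`.
#' @export
bin_spectrum <- function(spectrum, grid) {
  stopifnot(inherits(grid, "bin_grid"))
  out <- numeric(grid$n_bins)
  mz <- spectrum$mz
  keep <- mz >= grid$mz_min & mz < grid$mz_max
  if (!any(keep)) return(out)
  idx <- floor((mz[keep] - grid$mz_min) / grid$width) + 1
  idx[idx > grid$n_bins] <- grid$n_bins   # guards float round-up at the edge
  acc <- rowsum(spectrum$intensity[keep], idx)
  out[as.integer(rownames(acc))] <- acc[, 1L]
  out
}

#' Aggregate binned spectra over retention-time windows
#'
#' Spectra are grouped into half-open windows `[t0 + k*window,
#' t0 + (k+1)*window)` anchored at the first scan's retention time; each
#' nonempty window yields the elementwise arithmetic mean of its member
#' vectors (intensities summed across the window, then divided by the
#' number of scans). Empty windows produce no row.
#'
#' @param rts numeric vector of retention times (seconds, nondecreasing).
#' @param binned matrix with one row per spectrum (rows align with `rts`).
#' @param window window length in seconds (default 10).
#' @return matrix with one row per nonempty window, in window order.
#' @export
aggregate_rt <- function(rts, binned, window = 10) {
  stopifnot(window > 0)
  if (length(rts) == 0L) return(binned[0, , drop = FALSE])
  stopifnot(nrow(binned) == length(rts), !is.unsorted(rts))
  idx <- floor((rts - rts[1L]) / window)
  groups <- sort(unique(idx))
  out <- matrix(0, length(groups), ncol(binned))
  for (i in seq_along(groups)) {
    rows <- which(idx == groups[i])
    out[i, ] <- colSums(binned[rows, , drop = FALSE]) / length(rows)
  }
  out
}

#' Build a feature matrix from a set of runs
#'
#' `mode = "lcms"`: bin every scan, then aggregate over RT windows.
#' `mode = "spidermass"`: drop scans with TIC below `tic_threshold`, then
#' bin every retained scan (no RT aggregation). Every row carries its
#' run's label and file id; rows from different runs are never mixed.
#'
#' @param runs list of [ms_run()].
#' @param grid a [bin_grid()].
#' @param mode `"lcms"` or `"spidermass"`.
#' @param window RT window in seconds (lcms mode).
#' @param tic_threshold TIC threshold (spidermass mode).
#' @return an object of class `feature_matrix` with fields `values`
#'   (instances x bins), `labels`, `file_ids` and `grid`.
#' @export
build_feature_matrix <- function(runs, grid, mode = c("lcms", "spidermass"),
                                 window = 10, tic_threshold = 1e4) {
  mode <- match.arg(mode)
  stopifnot(length(runs) > 0L)
  blocks <- vector("list", length(runs))
  labels <- character(0)
  file_ids <- character(0)
  for (i in seq_along(runs)) {
    run <- runs[[i]]
    if (mode == "spidermass") run <- filter_low_tic(run, tic_threshold)
    binned <- t(vapply(run$spectra, bin_spectrum, numeric(grid$n_bins),
                       grid = grid))
    if (mode == "lcms") {
      rts <- vapply(run$spectra, function(s) s$rt, 1.0)
      binned <- aggregate_rt(rts, binned, window)
    }
    if (nrow(binned) == 0L) {
      stop("run '", run$file_id, "' yielded zero feature rows")
    }
    blocks[[i]] <- binned
    labels <- c(labels, rep(run$label, nrow(binned)))
    file_ids <- c(file_ids, rep(run$file_id, nrow(binned)))
  }
  feature_matrix(do.call(rbind, blocks), labels, file_ids, grid)
}

#' Construct a feature matrix object
#' @param values numeric matrix, instances x bins, all entries >= 0.
#' @param labels,file_ids per-row metadata.
#' @param grid the [bin_grid()] the columns refer to.
#' @return an object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, labels, file_ids, grid) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == length(labels), nrow(values) == length(file_ids))
  if (any(values < 0)) stop("feature matrix values must be >= 0")
  structure(list(values = values, labels = as.character(labels),
                 file_ids = as.character(file_ids), grid = grid),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("<feature_matrix> ", nrow(x$values), " instances x ", ncol(x$values),
      " bins (", x$grid$mz_min, "-", x$grid$mz_max, " Da @ ", x$grid$width,
      " Da), ", length(unique(x$labels)), " classes, ",
      length(unique(x$file_ids)), " files\n", sep = "")
  invisible(x)
}

#' TIC-normalize a feature matrix
#'
#' Divides each row by its own sum (relative abundance); nonzero rows then
#' sum to 1. All-zero rows are left unchanged with a warning.
#'
#' @param matrix a [feature_matrix()].
#' @return the normalized [feature_matrix()].
#' @export
tic_normalize <- function(matrix) {
  rs <- rowSums(matrix$values)
  zero <- rs == 0
  if (any(zero)) {
    warning(sum(zero), " all-zero rows left unnormalized")
    rs[zero] <- 1
  }
  matrix$values <- matrix$values / rs
  matrix
}

#' Export a feature matrix to a tabular file
#'
#' Tab-separated with a `label` and `file_id` column followed by one column
#' per bin, named by the bin's left edge. A `.gz` suffix compresses.
#'
#' @param fm a [feature_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  edges <- fm$grid$mz_min + (seq_len(fm$grid$n_bins) - 1L) * fm$grid$width
  df <- data.frame(label = fm$labels, file_id = fm$file_ids,
                   fm$values, check.names = FALSE)
  names(df)[-(1:2)] <- sprintf("%.6g", edges)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  writeLines(sprintf("# mz_min=%.10g mz_max=%.10g width=%.10g",
                     fm$grid$mz_min, fm$grid$mz_max, fm$grid$width), con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  close(con)
  invisible(path)
}

#' Import a feature matrix written by [write_feature_matrix()]
#' @param path input path.
#' @return a [feature_matrix()].
#' @export
read_feature_matrix <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  on.exit(close(con))
  hdr <- readLines(con, n = 1L)
  m <- regmatches(hdr, regexec(
    "mz_min=([0-9.eE+-]+) mz_max=([0-9.eE+-]+) width=([0-9.eE+-]+)", hdr))[[1L]]
  if (length(m) != 4L) stop("not a feature-matrix file: ", path)
  grid <- bin_grid(as.numeric(m[2L]), as.numeric(m[3L]), as.numeric(m[4L]))
  df <- utils::read.table(con, sep = "\t", header = TRUE, check.names = FALSE)
  feature_matrix(as.matrix(df[, -(1:2), drop = FALSE]),
                 df$label, df$file_id, grid)
}
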
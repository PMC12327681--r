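test_that("tic sums intensities and matches an elementwise oracle", {
  expect_identical(tic(ms_spectrum(c(1, 2, 3), c(1, 2, 3))), 6)
  expect_identical(tic(ms_spectrum(numeric(0), numeric(0))), 0)
  set.seed(9)
  s <- random_run(9, n_spectra = 1, n_peaks = 1000)$spectra[[1]]
  oracle <- 0
  for (v in s$intensity) oracle <- oracle + v
  expect_equal(tic(s), oracle)
})

test_that("filter_low_tic keeps TIC >= threshold, is idempotent, errors when empty", {
  mk <- function(total) ms_spectrum(c(100, 101), c(total / 2, total / 2), rt = 0)
  run <- ms_run(list(mk(9999), mk(10000), mk(20000)), "a", "f1")
  kept <- filter_low_tic(run, 1e4)
  expect_length(kept$spectra, 2L)   # boundary value retained: "below" is strict
  expect_equal(vapply(kept$spectra, tic, 1.0), c(10000, 20000))
  expect_identical(filter_low_tic(kept, 1e4)$spectra, kept$spectra)
  expect_length(filter_low_tic(run, 0)$spectra, 3L)
  expect_error(filter_low_tic(run, 1e9), "f1")
  # brute-force oracle on random runs
  for (seed in 1:10) {
    run <- random_run(seed, n_spectra = 8)
    thr <- stats::median(vapply(run$spectra, tic, 1.0))
    kept <- filter_low_tic(run, thr)
    oracle <- list()
    for (s in run$spectra) if (sum(s$intensity) >= thr) oracle <- c(oracle, list(s))
    expect_identical(kept$spectra, oracle)
  }
})

test_that("bin_spectrum follows the half-open convention and conserves intensity", {
  grid <- bin_grid(100, 1600, 0.1)
  expect_identical(grid$n_bins, 15000L)
  v <- bin_spectrum(ms_spectrum(c(100.04, 100.07), c(5, 7)), grid)
  expect_equal(v[1], 12)
  expect_equal(sum(v), 12)
  expect_equal(sum(v != 0), 1L)
  # peak exactly at mz_max is excluded (right edge open)
  expect_equal(sum(bin_spectrum(ms_spectrum(1600, 5), grid)), 0)
  # peak exactly at mz_min lands in bin 1
  expect_equal(bin_spectrum(ms_spectrum(100, 5), grid)[1], 5)
  # conservation + hand-binning oracle on random spectra
  for (seed in 1:20) {
    s <- random_run(seed, n_spectra = 1, n_peaks = 50,
                    mz_range = c(95, 1650))$spectra[[1]]
    v <- bin_spectrum(s, grid)
    in_range <- s$mz >= 100 & s$mz < 1600
    expect_equal(sum(v), sum(s$intensity[in_range]))
    oracle <- numeric(grid$n_bins)
    for (i in which(in_range)) {
      b <- 1L
      while (100 + b * 0.1 <= s$mz[i]) b <- b + 1L
      oracle[b] <- oracle[b] + s$intensity[i]
    }
    expect_equal(v, oracle)
  }
})

test_that("aggregate_rt groups into half-open windows anchored at the first rt", {
  m <- matrix(c(4, 6), 2, 1)
  expect_equal(aggregate_rt(c(0, 3), m, 10), matrix(5, 1, 1))
  one <- matrix(1:4, 1, 4)
  expect_equal(aggregate_rt(5, one, 10), one)
  # rts [0, 3, 10.0, 19.9] -> windows {0: [0,3], 1: [10.0, 19.9]}
  m4 <- matrix(c(1, 3, 10, 30), 4, 1)
  out <- aggregate_rt(c(0, 3, 10.0, 19.9), m4, 10)
  expect_equal(out, matrix(c(2, 20), 2, 1))
  # window assignment oracle on random rt vectors
  for (seed in 1:10) {
    set.seed(seed)
    rts <- sort(runif(30, 0, 120))
    mm <- matrix(runif(30 * 3), 30, 3)
    out <- aggregate_rt(rts, mm, 10)
    assign <- floor((rts - rts[1]) / 10)
    expected <- do.call(rbind, lapply(sort(unique(assign)), function(w) {
      colMeans(mm[assign == w, , drop = FALSE])
    }))
    expect_equal(out, expected)
  }
  # n identical vectors average to themselves
  rep10 <- matrix(rep(c(1, 2, 3), each = 5), 5, 3)
  expect_equal(aggregate_rt(rep(0:4), rep10, 10), rep10[1, , drop = FALSE])
})

test_that("build_feature_matrix keeps per-run bookkeeping in both modes", {
  grid <- bin_grid(100, 110, 0.1)
  mk_run <- function(id, label, rts) {
    ms_run(lapply(rts, function(t) ms_spectrum(c(102, 105), c(2e4, 3e4), rt = t)),
           label, id)
  }
  # lcms: 2 runs x 2 windows each
  runs <- list(mk_run("f1", "a", c(0, 1, 12)), mk_run("f2", "b", c(0, 15)))
  fm <- build_feature_matrix(runs, grid, mode = "lcms", window = 10)
  expect_equal(nrow(fm$values), 4L)
  expect_identical(fm$file_ids, c("f1", "f1", "f2", "f2"))
  expect_identical(fm$labels, c("a", "a", "b", "b"))
  # spidermass: low-TIC scans dropped, one row per retained scan
  low <- ms_spectrum(c(102, 105), c(10, 20), rt = 3)
  run <- ms_run(c(lapply(0:2, function(t) ms_spectrum(c(102, 105), c(2e4, 3e4), rt = t)),
                  list(low, ms_spectrum(103, 5, rt = 4))), "a", "f3")
  fm2 <- build_feature_matrix(list(run), grid, mode = "spidermass",
                              tic_threshold = 1e4)
  expect_equal(nrow(fm2$values), 3L)
  # lcms row total <= max member TIC (mean <= max)
  for (seed in 1:5) {
    run <- random_run(seed, n_spectra = 12, mz_range = c(100, 110))
    fm3 <- build_feature_matrix(list(run), grid, mode = "lcms", window = 5)
    tics <- vapply(run$spectra, tic, 1.0)
    expect_true(all(rowSums(fm3$values) <= max(tics) + 1e-9))
  }
})

test_that("tic_normalize makes nonzero rows sum to 1, warns on zero rows, idempotent", {
  grid <- bin_grid(0, 1, 0.5)
  fm <- feature_matrix(rbind(c(2, 2), c(1, 3)), c("a", "b"), c("f", "g"), grid)
  nm <- tic_normalize(fm)
  expect_equal(nm$values[1, ], c(0.5, 0.5))
  expect_equal(rowSums(nm$values), c(1, 1))
  expect_equal(tic_normalize(nm)$values, nm$values)
  fz <- feature_matrix(rbind(c(0, 0), c(1, 1)), c("a", "b"), c("f", "g"), grid)
  expect_warning(nz <- tic_normalize(fz), "all-zero")
  expect_equal(nz$values[1, ], c(0, 0))
  set.seed(4)
  big <- feature_matrix(matrix(rexp(200), 20, 10), rep("a", 20), rep("f", 20), grid)
  expect_true(all(abs(rowSums(tic_normalize(big)$values) - 1) < 1e-9))
})

test_that("feature matrix survives a file round trip", {
  set.seed(5)
  grid <- bin_grid(100, 101, 0.1)
  fm <- feature_matrix(matrix(runif(30), 3, 10),
                       c("a", "b", "a"), c("f1", "f2", "f3"), grid)
  path <- withr::local_tempfile(fileext = ".tsv.gz")
  write_feature_matrix(fm, path)
  back <- read_feature_matrix(path)
  expect_equal(back$values, fm$values, ignore_attr = TRUE, tolerance = 1e-12)
  expect_identical(back$labels, fm$labels)
  expect_identical(back$file_ids, fm$file_ids)
  expect_equal(back$grid$n_bins, fm$grid$n_bins)
})
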
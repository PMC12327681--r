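# Shared fixtures: everything is generated in code at test time.

# A small deterministic run with hand-chosen peaks.
tiny_run <- function(label = "a", file_id = "run1") {
  ms_run(list(
    ms_spectrum(c(100.04, 100.07, 101.25), c(5, 7, 3), rt = 0),
    ms_spectrum(c(100.55, 102.10), c(10, 2), rt = 1),
    ms_spectrum(c(100.01, 103.99), c(4, 6), rt = 2)
  ), label = label, file_id = file_id)
}

# Random valid run under a seed.
random_run <- function(seed, n_spectra = 5, n_peaks = 20,
                       mz_range = c(100, 200), label = "x", file_id = "rnd") {
  set.seed(seed)
  spectra <- lapply(seq_len(n_spectra), function(i) {
    mz <- sort(runif(n_peaks, mz_range[1], mz_range[2]))
    ms_spectrum(mz, rlnorm(n_peaks, log(100), 1), rt = i - 1)
  })
  ms_run(spectra, label = label, file_id = file_id)
}

# Tiny MSMCE configuration used for gradient checks.
tiny_cfg <- function(D = 8L) {
  msmce_config(D = D, hidden = 6L, d = 5L, C = 3L, C_mid = 2L,
               kernel = 3L, dropout_p = 0)
}

# relative error with an absolute floor so exactly-zero gradients (e.g. a
# conv bias immediately absorbed by batch norm) compare cleanly
rel_err <- function(a, b) max(abs(a - b)) / max(max(abs(b)), 1e-6)

expect_grad_matches <- function(param, fd, tol = 1e-4) {
  expect_false(is.null(param$grad))
  expect_lt(rel_err(param$grad, fd), tol)
}
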
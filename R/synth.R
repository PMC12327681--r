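# Synthetic labelled mass-spectrometry runs.
#
# The generator emulates the statistical structure the pipeline assumes:
# class-specific template peaks on the m/z axis, per-spectrum calibration
# jitter (a global m/z shift) plus optional per-peak scatter, log-normal
# intensity variability, uniform baseline noise peaks, TIC variation
# including a fraction of sub-threshold scans, and retention-time
# structure at a fixed scan spacing. It does not emulate isotope
# patterns, adducts or chromatographic peak shapes.

#' Specify a synthetic dataset
#'
#' @param n_classes number of classes.
#' @param files_per_class runs (files) per class.
#' @param spectra_per_file scans per run.
#' @param rt_spacing scan spacing in seconds (default 1.0).
#' @param mz_range mass range in Da, `c(lo, hi)`.
#' @param peaks_per_class characteristic peaks per class template.
#' @param shared_peaks background peaks common to all classes.
#' @param template_overlap fraction of each class template shared with a
#'   common pool (0 = disjoint templates, higher = harder task).
#' @param peak_sigma per-peak m/z scatter sd in Da.
#' @param jitter_sd per-spectrum global m/z shift sd in Da (calibration
#'   drift).
#' @param intensity_lognorm_sd log-normal sd of per-draw peak intensities.
#' @param baseline_n,baseline_level number and mean intensity share of
#'   uniform baseline noise peaks (`baseline_level` is the expected
#'   fraction of TIC contributed by baseline).
#' @param target_tic typical scan TIC before the low-TIC mechanism; scans
#'   draw their TIC log-normally around this value.
#' @param low_tic_fraction fraction of scans rescaled to TIC below 1e4.
#' @param seed integer seed.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_classes = 2L, files_per_class = 5L,
                           spectra_per_file = 20L, rt_spacing = 1.0,
                           mz_range = c(100, 300), peaks_per_class = 30L,
                           shared_peaks = 20L, template_overlap = 0,
                           peak_sigma = 0.01, jitter_sd = 0.02,
                           intensity_lognorm_sd = 0.4, baseline_n = 50L,
                           baseline_level = 0.05, target_tic = 1e6,
                           low_tic_fraction = 0.05, seed = 1L) {
  stopifnot(n_classes >= 1, files_per_class >= 1, spectra_per_file >= 1,
            rt_spacing > 0, length(mz_range) == 2L, mz_range[2L] > mz_range[1L],
            peaks_per_class >= 1, shared_peaks >= 0,
            template_overlap >= 0, template_overlap <= 1,
            low_tic_fraction >= 0, low_tic_fraction < 1)
  structure(as.list(environment()), class = "synthetic_spec")
}

#' Generate a labelled synthetic dataset
#'
#' Each class gets a fixed template of characteristic peak positions and
#' base intensities; each scan redraws peak intensities log-normally,
#' applies a global m/z jitter, adds shared background peaks and baseline
#' noise, and is rescaled to a log-normal TIC (a `low_tic_fraction` of
#' scans land below 1e4 instead). Deterministic given `spec$seed`.
#'
#' @param spec a [synthetic_spec()].
#' @return list of [ms_run()] objects (`n_classes * files_per_class`).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  rng <- local_rng(spec$seed)
  on.exit(rng())
  lo <- spec$mz_range[1L]
  hi <- spec$mz_range[2L]
  margin <- 0.02 * (hi - lo)
  rpos <- function(n) sort(stats::runif(n, lo + margin, hi - margin))
  if (spec$template_overlap > 0.8) {
    warning("class templates share > 80% of their peaks; classes may not be separable")
  }
  n_shared_tpl <- round(spec$template_overlap * spec$peaks_per_class)
  overlap_pool <- if (n_shared_tpl > 0) rpos(n_shared_tpl) else numeric(0)
  templates <- lapply(seq_len(spec$n_classes), function(cl) {
    own <- rpos(spec$peaks_per_class - n_shared_tpl)
    pos <- c(overlap_pool, own)
    list(pos = pos,
         base = stats::rlnorm(length(pos), meanlog = log(100), sdlog = 0.5))
  })
  bg_pos <- if (spec$shared_peaks > 0) rpos(spec$shared_peaks) else numeric(0)
  bg_base <- stats::rlnorm(length(bg_pos), meanlog = log(60), sdlog = 0.5)

  runs <- vector("list", spec$n_classes * spec$files_per_class)
  r <- 0L
  for (cl in seq_len(spec$n_classes)) {
    tpl <- templates[[cl]]
    for (f in seq_len(spec$files_per_class)) {
      spectra <- vector("list", spec$spectra_per_file)
      for (i in seq_len(spec$spectra_per_file)) {
        shift <- stats::rnorm(1L, 0, spec$jitter_sd)
        pos <- c(tpl$pos, bg_pos) + shift +
          stats::rnorm(length(tpl$pos) + length(bg_pos), 0, spec$peak_sigma)
        inten <- c(tpl$base, bg_base) *
          stats::rlnorm(length(pos), 0, spec$intensity_lognorm_sd)
        if (spec$baseline_n > 0 && spec$baseline_level > 0) {
          bl_pos <- stats::runif(spec$baseline_n, lo + margin, hi - margin)
          bl_mean <- spec$baseline_level * sum(inten) / spec$baseline_n
          pos <- c(pos, bl_pos)
          inten <- c(inten, stats::rexp(spec$baseline_n, 1 / bl_mean))
        }
        keep <- pos > lo & pos < hi
        pos <- pos[keep]
        inten <- inten[keep]
        o <- order(pos)
        pos <- pos[o]
        inten <- inten[o]
        # merge accidental exact collisions so m/z stays strictly increasing
        if (anyDuplicated(pos)) {
          inten <- as.vector(rowsum(inten, match(pos, unique(pos))))
          pos <- unique(pos)
        }
        tic_target <- if (stats::runif(1L) < spec$low_tic_fraction) {
          stats::runif(1L, 1e3, 9e3)
        } else {
          stats::rlnorm(1L, log(spec$target_tic), 0.3)
        }
        inten <- inten * tic_target / sum(inten)
        spectra[[i]] <- ms_spectrum(pos, inten, rt = (i - 1L) * spec$rt_spacing)
      }
      r <- r + 1L
      runs[[r]] <- ms_run(spectra, label = paste0("class", cl),
                          file_id = sprintf("class%d_f%d", cl, f))
    }
  }
  runs
}

benchmark_profiles <- list(
  easy = list(
    synth = list(n_classes = 2L, files_per_class = 5L, spectra_per_file = 20L,
                 mz_range = c(100, 300), peaks_per_class = 30L,
                 shared_peaks = 20L, template_overlap = 0,
                 jitter_sd = 0.02, intensity_lognorm_sd = 0.4,
                 low_tic_fraction = 0.05),
    mode = "spidermass"
  ),
  hard = list(
    synth = list(n_classes = 4L, files_per_class = 4L, spectra_per_file = 15L,
                 mz_range = c(100, 200), peaks_per_class = 12L,
                 shared_peaks = 30L, template_overlap = 0.75,
                 jitter_sd = 0.08, intensity_lognorm_sd = 1.0,
                 low_tic_fraction = 0.05),
    mode = "spidermass"
  ),
  `collapse-prone` = list(
    synth = list(n_classes = 2L, files_per_class = 5L, spectra_per_file = 20L,
                 mz_range = c(100, 500), peaks_per_class = 25L,
                 shared_peaks = 40L, template_overlap = 0.3,
                 jitter_sd = 0.05, intensity_lognorm_sd = 0.6,
                 low_tic_fraction = 0.05),
    mode = "spidermass"
  )
)

#' Build a named benchmark: synthetic runs -> preprocessed matrix splits
#'
#' Generates a profile's runs, pushes them through the real preprocessing
#' workflow (TIC filter / binning per the profile's mode), TIC-normalizes,
#' and splits at the file level into train and hold-out matrices.
#'
#' Profiles: `easy` (2 well-separated classes, ~2000 bins, ~200
#' instances), `hard` (4 classes with half-overlapping templates and few
#' files per class), `collapse-prone` (2 classes on a wide 4000-bin range,
#' sized to stress sequence baselines on raw input).
#'
#' @param profile one of `"easy"`, `"hard"`, `"collapse-prone"`.
#' @param seed integer seed.
#' @param bin_width m/z bin width in Da (default 0.1).
#' @param test_frac hold-out fraction of files per class (default 0.10).
#' @return list with `train` and `test` ([feature_matrix()], normalized),
#'   and `meta` (profile, mode, grid, file split, seed).
#' @export
make_benchmark <- function(profile = c("easy", "hard", "collapse-prone"),
                           seed = 1L, bin_width = 0.1, test_frac = 0.10) {
  profile <- match.arg(profile)
  prof <- benchmark_profiles[[profile]]
  spec <- do.call(synthetic_spec, c(prof$synth, list(seed = seed)))
  runs <- generate_dataset(spec)
  grid <- bin_grid(spec$mz_range[1L], spec$mz_range[2L], bin_width)
  labels <- vapply(runs, function(r) r$label, "")
  ids <- vapply(runs, function(r) r$file_id, "")
  split <- stratified_file_split(
    data.frame(file_id = ids, label = labels), test_frac, seed = seed)
  fm <- function(sel) {
    tic_normalize(build_feature_matrix(runs[sel], grid, mode = prof$mode))
  }
  list(train = fm(ids %in% split$train_files),
       test = fm(ids %in% split$test_files),
       meta = list(profile = profile, mode = prof$mode, grid = grid,
                   split = split, seed = seed, spec = spec))
}
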
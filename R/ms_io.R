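# Reading and writing mass-spectrometry runs.
#
# Two on-disk representations are supported: standard mzML (read-only,
# MS1 scans) and a line-oriented JSON fixture format used by the synthetic
# generator and the test suite.

#' Construct a single mass spectrum
#'
#' A spectrum is a scan: parallel vectors of m/z (Da, strictly increasing)
#' and non-negative intensities, plus a retention time in seconds.
#'
#' @param mz numeric vector of m/z values in Da.
#' @param intensity numeric vector of intensities, same length as `mz`.
#' @param rt scan retention time in seconds.
#' @return an object of class `ms_spectrum`.
#' @export
ms_spectrum <- function(mz, intensity, rt = 0) {
  mz <- as.numeric(mz)
  intensity <- as.numeric(intensity)
  if (length(mz) != length(intensity)) {
    stop("mz and intensity must have the same length (", length(mz),
         " vs ", length(intensity), ")")
  }
  if (length(rt) != 1L || !is.finite(rt) || rt < 0) {
    stop("rt must be a single finite non-negative number of seconds")
  }
  if (any(!is.finite(mz)) || any(!is.finite(intensity))) {
    stop("mz and intensity must be finite")
  }
  if (any(intensity < 0)) stop("intensities must be >= 0")
  if (is.unsorted(mz, strictly = TRUE)) {
    o <- order(mz)
    mz <- mz[o]
    intensity <- intensity[o]
    if (anyDuplicated(mz)) stop("duplicate m/z values within one scan")
    warning("m/z values were not strictly increasing; peaks re-sorted by m/z")
  }
  structure(list(mz = mz, intensity = intensity, rt = as.numeric(rt)),
            class = "ms_spectrum")
}

#' Construct a run (one file's worth of spectra with a class label)
#'
#' @param spectra list of [ms_spectrum()] objects.
#' @param label class label for the whole run (character scalar).
#' @param file_id identifier of the source file.
#' @return an object of class `ms_run`.
#' @export
ms_run <- function(spectra, label, file_id) {
  if (length(spectra) == 0L) stop("empty run: a run must contain at least one spectrum")
  stopifnot(all(vapply(spectra, inherits, TRUE, "ms_spectrum")))
  rts <- vapply(spectra, function(s) s$rt, 1.0)
  if (is.unsorted(rts)) spectra <- spectra[order(rts)]
  structure(list(spectra = spectra, label = as.character(label),
                 file_id = as.character(file_id)),
            class = "ms_run")
}

#' @export
print.ms_run <- function(x, ...) {
  rts <- vapply(x$spectra, function(s) s$rt, 1.0)
  cat("<ms_run> file_id=", x$file_id, " label=", x$label,
      " spectra=", length(x$spectra),
      " rt=[", min(rts), ", ", max(rts), "] s\n", sep = "")
  invisible(x)
}

#' Read a mass-spectrometry run from disk
#'
#' @param path path to an mzML or fixture file.
#' @param format `"mzml"` or `"fixture"`; `"auto"` guesses from the
#'   extension (`.mzML` vs anything else).
#' @param label,file_id overrides for the run metadata; the fixture format
#'   stores both, mzML stores neither so they default to the file name and
#'   `"unknown"`.
#' @return an [ms_run()] with spectra sorted by retention time (seconds).
#' @export
read_run <- function(path, format = c("auto", "mzml", "fixture"),
                     label = NULL, file_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.mzml$", path, ignore.case = TRUE)) "mzml" else "fixture"
  }
  run <- switch(format,
    fixture = read_fixture(path),
    mzml = read_mzml(path, label = label, file_id = file_id)
  )
  if (!is.null(label)) run$label <- as.character(label)
  if (!is.null(file_id)) run$file_id <- as.character(file_id)
  run
}

# Fixture format: line 1 is a JSON header {"label": ..., "file_id": ...};
# each following line is one scan {"rt": ..., "mz": [...], "intensity": [...]}.
# Numbers are written with 15 significant digits so round trips are exact
# at double precision.
read_fixture <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("empty run: fixture file ", path, " has no scans")
  hdr <- jsonlite::fromJSON(lines[[1L]])
  spectra <- lapply(lines[-1L], function(ln) {
    rec <- jsonlite::fromJSON(ln)
    ms_spectrum(as.numeric(rec$mz), as.numeric(rec$intensity), as.numeric(rec$rt))
  })
  ms_run(spectra, label = hdr$label, file_id = hdr$file_id)
}

#' Write a run in the line-oriented fixture format
#'
#' One JSON object per line: a header with label and file id, then one
#' line per scan. `read_run(write_fixture(run))` reproduces `run` exactly.
#'
#' @param run an [ms_run()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fixture <- function(run, path) {
  stopifnot(inherits(run, "ms_run"))
  if (length(run$spectra) == 0L) stop("empty run: refusing to write a run with no spectra")
  con <- file(path, "w")
  on.exit(close(con))
  num <- function(x) {
    # 17 significant digits round-trips IEEE doubles exactly
    paste0("[", paste(formatC(x, digits = 17, format = "g"), collapse = ","), "]")
  }
  writeLines(jsonlite::toJSON(list(label = run$label, file_id = run$file_id),
                              auto_unbox = TRUE), con)
  for (s in run$spectra) {
    writeLines(sprintf('{"rt":%s,"mz":%s,"intensity":%s}',
                       formatC(s$rt, digits = 17, format = "g"),
                       num(s$mz), num(s$intensity)), con)
  }
  invisible(path)
}

# ---- mzML ------------------------------------------------------------------

# Minimal mzML reader: MS1 spectra only (MSn scans are skipped with a
# warning), base64-encoded 32/64-bit float arrays, optional zlib
# compression, retention times converted to seconds.
read_mzml <- function(path, label = NULL, file_id = NULL) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  nodes <- xml2::xml_find_all(doc, ".//spectrum")
  if (length(nodes) == 0L) stop("empty run: no spectra in mzML file ", path)
  n_msn <- 0L
  spectra <- list()
  for (nd in nodes) {
    lvl <- cv_value(nd, "MS:1000511")
    if (!is.na(lvl) && as.integer(lvl) != 1L) {
      n_msn <- n_msn + 1L
      next
    }
    rt <- NA_real_
    scan <- xml2::xml_find_first(nd, ".//scanList/scan")
    if (!inherits(scan, "xml_missing")) {
      p <- xml2::xml_find_first(
        scan, ".//cvParam[@accession='MS:1000016']")
      if (!inherits(p, "xml_missing")) {
        rt <- as.numeric(xml2::xml_attr(p, "value"))
        unit <- xml2::xml_attr(p, "unitName")
        if (!is.na(unit) && grepl("min", unit, ignore.case = TRUE)) rt <- rt * 60
      }
    }
    if (is.na(rt)) rt <- 0
    arrays <- xml2::xml_find_all(nd, ".//binaryDataArray")
    mz <- NULL
    inten <- NULL
    for (arr in arrays) {
      vals <- decode_binary_array(arr)
      if (has_cv(arr, "MS:1000514")) mz <- vals
      if (has_cv(arr, "MS:1000515")) inten <- vals
    }
    if (is.null(mz) || is.null(inten)) next
    spectra[[length(spectra) + 1L]] <- ms_spectrum(mz, inten, rt)
  }
  if (n_msn > 0L) {
    warning(n_msn, " MSn spectra ignored (only MS1 scans are read)")
  }
  if (length(spectra) == 0L) stop("empty run: no MS1 spectra in ", path)
  ms_run(spectra,
         label = if (is.null(label)) "unknown" else label,
         file_id = if (is.null(file_id)) basename(path) else file_id)
}

has_cv <- function(node, accession) {
  p <- xml2::xml_find_first(node, sprintf(".//cvParam[@accession='%s']", accession))
  !inherits(p, "xml_missing")
}

cv_value <- function(node, accession) {
  p <- xml2::xml_find_first(node, sprintf(".//cvParam[@accession='%s']", accession))
  if (inherits(p, "xml_missing")) return(NA_character_)
  xml2::xml_attr(p, "value")
}

decode_binary_array <- function(arr) {
  b64 <- xml2::xml_text(xml2::xml_find_first(arr, ".//binary"))
  raw <- jsonlite::base64_dec(gsub("\\s", "", b64))
  if (has_cv(arr, "MS:1000574")) raw <- memDecompress(raw, type = "gzip")
  size <- if (has_cv(arr, "MS:1000521")) 4L else 8L
  readBin(raw, what = "double", n = length(raw) %/% size, size = size,
          endian = "little")
}

# Writes a minimal, schema-light mzML document (synthetic output for reader
# integration tests; not a general-purpose exporter).
write_mzml_minimal <- function(run, path, precision = c("64", "32"),
                               compress = FALSE) {
  precision <- match.arg(precision)
  size <- if (precision == "64") 8L else 4L
  enc <- function(x) {
    r <- writeBin(as.numeric(x), raw(), size = size, endian = "little")
    if (compress) r <- memCompress(r, type = "gzip")
    jsonlite::base64_enc(r)
  }
  cv_prec <- if (precision == "64") {
    '<cvParam accession="MS:1000523" name="64-bit float" value=""/>'
  } else {
    '<cvParam accession="MS:1000521" name="32-bit float" value=""/>'
  }
  cv_comp <- if (compress) {
    '<cvParam accession="MS:1000574" name="zlib compression" value=""/>'
  } else {
    '<cvParam accession="MS:1000576" name="no compression" value=""/>'
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines('<?xml version="1.0" encoding="utf-8"?>', con)
  writeLines(sprintf('<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0"><run id="%s"><spectrumList count="%d">',
                     run$file_id, length(run$spectra)), con)
  for (i in seq_along(run$spectra)) {
    s <- run$spectra[[i]]
    writeLines(sprintf('<spectrum index="%d" id="scan=%d" defaultArrayLength="%d">', i - 1L, i, length(s$mz)), con)
    writeLines('<cvParam accession="MS:1000511" name="ms level" value="1"/>', con)
    writeLines(sprintf('<scanList count="1"><scan><cvParam accession="MS:1000016" name="scan start time" value="%.10g" unitName="minute"/></scan></scanList>',
                       s$rt / 60), con)
    writeLines('<binaryDataArrayList count="2">', con)
    writeLines(sprintf('<binaryDataArray>%s%s<cvParam accession="MS:1000514" name="m/z array" value=""/><binary>%s</binary></binaryDataArray>',
                       cv_prec, cv_comp, enc(s$mz)), con)
    writeLines(sprintf('<binaryDataArray>%s%s<cvParam accession="MS:1000515" name="intensity array" value=""/><binary>%s</binary></binaryDataArray>',
                       cv_prec, cv_comp, enc(s$intensity)), con)
    writeLines('</binaryDataArrayList></spectrum>', con)
  }
  writeLines('</spectrumList></run></mzML>', con)
  invisible(path)
}
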
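#' Binned 1D NMR spectrum
#'
#' Container for a 1D \eqn{^1}H NMR spectrum on a uniform ppm grid, the way
#' spectra arrive after phasing, shim adjustment and spectral binning in an
#' external processing suite.  Intensities are stored in \emph{ascending} ppm
#' order regardless of the order in the source file; bin indices are 0-based
#' so that \eqn{ppm(b) = ppm\_start + b \cdot bin\_width}.
#'
#' @param ppm_start ppm of bin 0 (the lowest-ppm bin).
#' @param bin_width ppm per bin, positive.  Typical value for finely binned
#'   plasma spectra is 0.0002 ppm/bin.
#' @param intensities numeric vector of relative intensities, length >= 2.
#' @param spectrometer_freq spectrometer frequency in MHz, used for Hz/ppm
#'   conversion of line widths (600 MHz by default).
#' @param id spectrum label.
#' @return An object of class `binned_spectrum`.
#' @export
binned_spectrum <- function(ppm_start, bin_width, intensities,
                            spectrometer_freq = 600, id = "spectrum") {
  if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width <= 0)
    stop("`bin_width` must be a single positive number", call. = FALSE)
  if (!is.numeric(intensities) || length(intensities) < 2L)
    stop("`intensities` must be numeric with length >= 2", call. = FALSE)
  if (!is.numeric(spectrometer_freq) || spectrometer_freq <= 0)
    stop("`spectrometer_freq` must be positive (MHz)", call. = FALSE)
  structure(
    list(ppm_start = as.numeric(ppm_start),
         bin_width = as.numeric(bin_width),
         intensities = as.numeric(intensities),
         spectrometer_freq = as.numeric(spectrometer_freq),
         id = as.character(id)),
    class = "binned_spectrum")
}

#' @export
print.binned_spectrum <- function(x, ...) {
  cat(sprintf("<binned_spectrum '%s': %d bins, %.4f..%.4f ppm, %.4g ppm/bin, %g MHz>\n",
              x$id, n_bins(x), x$ppm_start, ppm_end(x), x$bin_width,
              x$spectrometer_freq))
  invisible(x)
}

#' Number of bins in a spectrum
#' @param spectrum a `binned_spectrum`.
#' @return integer bin count.
#' @export
n_bins <- function(spectrum) length(spectrum$intensities)

#' ppm of the last bin
#' @inheritParams n_bins
#' @return ppm value of the highest bin centre.
#' @export
ppm_end <- function(spectrum)
  spectrum$ppm_start + (n_bins(spectrum) - 1L) * spectrum$bin_width

#' Full ppm axis
#' @inheritParams n_bins
#' @return numeric vector of bin-centre ppm values, ascending.
#' @export
ppm_axis <- function(spectrum)
  spectrum$ppm_start + (seq_len(n_bins(spectrum)) - 1) * spectrum$bin_width

#' Convert between ppm and bin index
#'
#' `ppm_to_bin()` maps a ppm value to the nearest 0-based bin index; ties at
#' half a bin round away from the lower index, so the mapping is deterministic
#' and monotone.  `bin_to_ppm()` is its right inverse on integer bins.
#'
#' @param spectrum a `binned_spectrum`.
#' @param ppm numeric vector of ppm values within the axis range (half a bin
#'   of slack is allowed at either end).
#' @return integer vector of bin indices.
#' @export
ppm_to_bin <- function(spectrum, ppm) {
  lo <- spectrum$ppm_start - spectrum$bin_width / 2
  hi <- ppm_end(spectrum) + spectrum$bin_width / 2
  if (any(ppm < lo | ppm > hi))
    stop(sprintf("ppm value outside axis range [%.6f, %.6f]",
                 spectrum$ppm_start, ppm_end(spectrum)), call. = FALSE)
  b <- as.integer(floor((ppm - spectrum$ppm_start) / spectrum$bin_width + 0.5))
  pmin.int(pmax.int(b, 0L), n_bins(spectrum) - 1L)
}

#' @rdname ppm_to_bin
#' @param bin integer vector of 0-based bin indices.
#' @export
bin_to_ppm <- function(spectrum, bin) {
  if (any(bin < 0L | bin > n_bins(spectrum) - 1L))
    stop("bin index out of range", call. = FALSE)
  spectrum$ppm_start + as.numeric(bin) * spectrum$bin_width
}

#' Intensity at (nearest bin of) given ppm positions
#' @inheritParams ppm_to_bin
#' @return numeric vector of intensities.
#' @export
intensity_at <- function(spectrum, ppm)
  spectrum$intensities[ppm_to_bin(spectrum, ppm) + 1L]

#' Extract a ppm sub-region of a spectrum
#'
#' Returns the bins whose centres are nearest to `lo_ppm` and `hi_ppm` and
#' everything between them, as a new `binned_spectrum` on the same grid.
#'
#' @inheritParams n_bins
#' @param lo_ppm,hi_ppm region bounds, `lo_ppm < hi_ppm`, overlapping the axis.
#' @return a `binned_spectrum` covering the region.
#' @export
slice_region <- function(spectrum, lo_ppm, hi_ppm) {
  if (lo_ppm >= hi_ppm)
    stop("`lo_ppm` must be smaller than `hi_ppm`", call. = FALSE)
  if (hi_ppm < spectrum$ppm_start || lo_ppm > ppm_end(spectrum))
    stop("region does not overlap the spectrum", call. = FALSE)
  b_lo <- ppm_to_bin(spectrum, max(lo_ppm, spectrum$ppm_start))
  b_hi <- ppm_to_bin(spectrum, min(hi_ppm, ppm_end(spectrum)))
  binned_spectrum(
    ppm_start = bin_to_ppm(spectrum, b_lo),
    bin_width = spectrum$bin_width,
    intensities = spectrum$intensities[(b_lo + 1L):(b_hi + 1L)],
    spectrometer_freq = spectrum$spectrometer_freq,
    id = spectrum$id)
}

#' Hz / ppm line-width conversion
#'
#' On a spectrometer operating at `freq_mhz`, a width of 1 Hz corresponds to
#' `1/freq_mhz` ppm (at 600 MHz, 1.2 Hz = 0.002 ppm).
#'
#' @param hz,ppm width values.
#' @param freq_mhz spectrometer frequency in MHz.
#' @return converted width.
#' @export
hz_to_ppm <- function(hz, freq_mhz) hz / freq_mhz

#' @rdname hz_to_ppm
#' @export
ppm_to_hz <- function(ppm, freq_mhz) ppm * freq_mhz

# ---- I/O -------------------------------------------------------------------

.detect_sep <- function(line) {
  if (grepl(",", line, fixed = TRUE)) "," else if (grepl("\t", line, fixed = TRUE)) "\t" else ""
}

#' Read a binned spectrum from disk
#'
#' Two dialects are supported.  `"xy"` is a two-column (ppm, intensity)
#' CSV/TSV/whitespace table, with or without a header line; the ppm column
#' must form an arithmetic progression (checked to 1e-9 ppm) and may run in
#' either direction -- descending files, the NMR convention, are flipped to
#' ascending storage.  `"dense"` is one intensity per line accompanied by a
#' JSON sidecar `<path>.json` holding `ppm_start`, `bin_width`,
#' `spectrometer_freq_mhz` and `id`.
#'
#' @param path file path.
#' @param dialect `"auto"` (default; dense when the sidecar exists), `"xy"`
#'   or `"dense"`.
#' @param spectrometer_freq frequency in MHz for the xy dialect, which does
#'   not carry it in-band.
#' @param id spectrum label; defaults to the file name without extension.
#' @return a `binned_spectrum`.
#' @export
read_binned_spectrum <- function(path, dialect = c("auto", "xy", "dense"),
                                 spectrometer_freq = 600, id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    stop(sprintf("spectrum file not found: %s", path), call. = FALSE)
  if (is.null(id))
    id <- sub("\\.[^.]*$", "", basename(path))
  sidecar <- paste0(path, ".json")
  if (dialect == "auto")
    dialect <- if (file.exists(sidecar)) "dense" else "xy"

  if (dialect == "dense") {
    if (!file.exists(sidecar))
      stop(sprintf("dense dialect requires sidecar %s", sidecar), call. = FALSE)
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    vals <- scan(path, what = double(), quiet = TRUE)
    return(binned_spectrum(
      ppm_start = meta$ppm_start, bin_width = meta$bin_width,
      intensities = vals,
      spectrometer_freq = meta$spectrometer_freq_mhz %||% spectrometer_freq,
      id = meta$id %||% id))
  }

  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L)
    stop(sprintf("parse error in %s: fewer than two data rows", path),
         call. = FALSE)
  sep <- .detect_sep(lines[[1L]])
  split1 <- strsplit(trimws(lines[[1L]]),
                     if (sep == "") "[[:space:]]+" else sep)[[1L]]
  skip <- if (suppressWarnings(anyNA(as.numeric(split1)))) 1L else 0L
  rows <- lines[(skip + 1L):length(lines)]
  parsed <- strsplit(trimws(rows), if (sep == "") "[[:space:]]+" else sep)
  for (i in seq_along(parsed)) {
    v <- suppressWarnings(as.numeric(parsed[[i]]))
    if (length(v) < 2L || anyNA(v[1:2]))
      stop(sprintf("parse error in %s at line %d: '%s'",
                   path, i + skip, rows[[i]]), call. = FALSE)
    parsed[[i]] <- v[1:2]
  }
  m <- do.call(rbind, parsed)
  ppm <- m[, 1L]; y <- m[, 2L]
  d <- diff(ppm)
  if (length(unique(sign(d))) != 1L || any(abs(d - d[1L]) > 1e-9))
    stop(sprintf("grid error in %s: ppm column is not a uniform progression",
                 path), call. = FALSE)
  if (d[1L] < 0) { ppm <- rev(ppm); y <- rev(y) }
  binned_spectrum(ppm_start = ppm[1L], bin_width = abs(d[1L]),
                  intensities = y, spectrometer_freq = spectrometer_freq,
                  id = id)
}

#' Write a binned spectrum to disk
#'
#' Inverse of [read_binned_spectrum()].  Values are written with 17
#' significant digits so that a read-back round trip is bit-exact.
#'
#' @param spectrum a `binned_spectrum`.
#' @param path output file path.
#' @param dialect `"xy"` (two-column CSV) or `"dense"` (intensity-per-line
#'   with JSON sidecar).
#' @return `path`, invisibly.
#' @export
write_binned_spectrum <- function(spectrum, path, dialect = c("xy", "dense")) {
  dialect <- match.arg(dialect)
  if (dialect == "xy") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("ppm,intensity", con)
    writeLines(paste(sprintf("%.17g", ppm_axis(spectrum)),
                     sprintf("%.17g", spectrum$intensities), sep = ","), con)
  } else {
    writeLines(sprintf("%.17g", spectrum$intensities), path)
    jsonlite::write_json(
      list(ppm_start = spectrum$ppm_start, bin_width = spectrum$bin_width,
           spectrometer_freq_mhz = spectrum$spectrometer_freq,
           id = spectrum$id),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- target table ----------------------------------------------------------

#' Target-signal table
#'
#' One row per targeted compound: the preselected target-signal position, the
#' half-width of the search window used during peak picking, and whether the
#' signal position is stable (`"constant"`) or drifts between spectra
#' (`"variable"`).
#'
#' @param compound_id character vector of compound identifiers.
#' @param nominal_ppm expected target positions (ppm).
#' @param window_ppm positive search-window half-widths (ppm).  Conventional
#'   defaults are one bin (0.0002 ppm) for constant targets and 15 bins
#'   (0.0030 ppm) for variable compounds.
#' @param variability `"constant"` or `"variable"`, recycled.
#' @return a `data.frame` with class `target_table`.
#' @export
target_table <- function(compound_id, nominal_ppm, window_ppm,
                         variability = "constant") {
  if (any(window_ppm <= 0)) stop("`window_ppm` must be positive", call. = FALSE)
  variability <- rep_len(as.character(variability), length(compound_id))
  if (!all(variability %in% c("constant", "variable")))
    stop("`variability` must be 'constant' or 'variable'", call. = FALSE)
  out <- data.frame(compound_id = as.character(compound_id),
                    nominal_ppm = as.numeric(nominal_ppm),
                    window_ppm = as.numeric(window_ppm),
                    variability = variability,
                    stringsAsFactors = FALSE)
  class(out) <- c("target_table", "data.frame")
  out
}

#' Read / write a target table
#'
#' CSV or TSV with columns `compound_id`, `nominal_ppm`, `window_ppm`,
#' `variability`.
#'
#' @param path file path.
#' @return a `target_table`.
#' @export
read_targets <- function(path) {
  if (!file.exists(path))
    stop(sprintf("target table not found: %s", path), call. = FALSE)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("compound_id", "nominal_ppm", "window_ppm", "variability")
  if (!all(need %in% names(df)))
    stop(sprintf("target table %s lacks columns: %s", path,
                 paste(setdiff(need, names(df)), collapse = ", ")),
         call. = FALSE)
  target_table(df$compound_id, df$nominal_ppm, df$window_ppm, df$variability)
}

#' @rdname read_targets
#' @param targets a `target_table`.
#' @export
write_targets <- function(targets, path) {
  utils::write.table(as.data.frame(targets), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
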
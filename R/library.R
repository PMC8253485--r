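#' Lorentzian signal
#'
#' One NMR line parameterized as a Lorentzian: intensity
#' \eqn{I(\delta) = h \, (w/2)^2 / ((\delta-\delta_0)^2 + (w/2)^2)} with
#' centre \eqn{\delta_0} (ppm), full width at half maximum \eqn{w} (Hz) and
#' apex height \eqn{h}.
#'
#' @param center_ppm centre position (ppm).
#' @param fwhm_hz full width at half maximum (Hz), positive.
#' @param height apex height (relative intensity), non-negative.
#' @return a one-row data.frame with columns `center_ppm`, `fwhm_hz`,
#'   `rel_height`.
#' @export
lorentzian_signal <- function(center_ppm, fwhm_hz, height = 1) {
  if (any(fwhm_hz <= 0)) stop("`fwhm_hz` must be positive", call. = FALSE)
  if (any(height < 0)) stop("`height` must be non-negative", call. = FALSE)
  data.frame(center_ppm = as.numeric(center_ppm),
             fwhm_hz = as.numeric(fwhm_hz),
             rel_height = as.numeric(height))
}

# Closed-form sum of Lorentzians evaluated at arbitrary ppm values.
# `signals` is a data.frame with center_ppm, fwhm_hz, rel_height.
.lorentzian_eval <- function(ppm, signals, freq_mhz) {
  out <- numeric(length(ppm))
  if (is.null(signals) || nrow(signals) == 0L) return(out)
  for (s in seq_len(nrow(signals))) {
    hw <- hz_to_ppm(signals$fwhm_hz[s], freq_mhz) / 2
    out <- out + signals$rel_height[s] * hw^2 /
      ((ppm - signals$center_ppm[s])^2 + hw^2)
  }
  out
}

#' Synthesize a spectrum from Lorentzian signals
#'
#' Evaluates the closed-form sum of Lorentzians at the bin centres of the
#' template axis.  Widths are given in Hz and converted to ppm using the
#' template's spectrometer frequency.
#'
#' @param signals data.frame of Lorentzians (see [lorentzian_signal()]); may
#'   have zero rows, giving an all-zero spectrum.
#' @param axis a `binned_spectrum` used as the grid template (its intensities
#'   are ignored).
#' @return a `binned_spectrum`.
#' @export
synthesize_spectrum <- function(signals, axis) {
  if (!is.null(signals) && nrow(signals) > 0L) {
    if (any(signals$center_ppm < axis$ppm_start |
            signals$center_ppm > ppm_end(axis)))
      stop("signal centre outside the axis range", call. = FALSE)
  }
  binned_spectrum(
    ppm_start = axis$ppm_start, bin_width = axis$bin_width,
    intensities = .lorentzian_eval(ppm_axis(axis), signals,
                                   axis$spectrometer_freq),
    spectrometer_freq = axis$spectrometer_freq, id = axis$id)
}

#' Library compound entry
#'
#' One targeted compound: its calibration spectrum (either a list of
#' Lorentzian signals -- preferred, exact re-synthesis without grid aliasing
#' -- or a measured `binned_spectrum`), the position of the reporter signal,
#' the concentration response factor, and two classifications used downstream:
#' `variability` decides whether the interference-matrix elements of the
#' compound are re-derived per spectrum, and `compound_class` separates
#' metabolites (quantified, and one interference source) from non-metabolites
#' such as the EDTA species (never interpreted quantitatively, the other
#' interference source).
#'
#' @param compound_id identifier.
#' @param signals data.frame of Lorentzians with `rel_height` relative to the
#'   reporter signal, or `NULL` when `spectrum` is given.
#' @param spectrum a measured calibration `binned_spectrum`, or `NULL`.
#' @param reporter_ppm position of the reporter (= target) signal.
#' @param response_factor concentration per unit normalized reporter height
#'   (micromolar per unit).  Required (positive) for metabolites; may be `NA`
#'   for non-metabolites.
#' @param variability `"constant"` or `"variable"`.
#' @param compound_class `"metabolite"` or `"nonmetabolite"`.
#' @return a `compound_entry`.
#' @export
compound_entry <- function(compound_id, signals = NULL, spectrum = NULL,
                           reporter_ppm, response_factor = NA_real_,
                           variability = c("constant", "variable"),
                           compound_class = c("metabolite", "nonmetabolite")) {
  variability <- match.arg(variability)
  compound_class <- match.arg(compound_class)
  if (is.null(signals) == is.null(spectrum))
    stop("exactly one of `signals` or `spectrum` must be given", call. = FALSE)
  if (compound_class == "metabolite" &&
      (!is.numeric(response_factor) || is.na(response_factor) ||
       response_factor <= 0))
    stop(sprintf("metabolite '%s' needs a positive response factor",
                 compound_id), call. = FALSE)
  structure(
    list(compound_id = as.character(compound_id), signals = signals,
         spectrum = spectrum, reporter_ppm = as.numeric(reporter_ppm),
         response_factor = as.numeric(response_factor),
         variability = variability, compound_class = compound_class),
    class = "compound_entry")
}

#' @export
print.compound_entry <- function(x, ...) {
  cat(sprintf("<compound '%s' (%s, %s): reporter %.4f ppm, %s signal(s)>\n",
              x$compound_id, x$compound_class, x$variability, x$reporter_ppm,
              if (is.null(x$signals)) "binned" else nrow(x$signals)))
  invisible(x)
}

# Raw (un-normalized) calibration height of an entry at given ppm positions.
.cal_height_raw <- function(entry, ppm, freq_mhz) {
  if (!is.null(entry$signals))
    .lorentzian_eval(ppm, entry$signals, freq_mhz)
  else
    intensity_at(entry$spectrum, ppm)
}

#' Normalize a calibration spectrum to unit reporter height
#'
#' Each calibration spectrum is scaled so that its reporter-signal height is
#' exactly 1, which makes matrix columns dimensionless relative heights and
#' ties the reporter height linearly to concentration via the response factor.
#'
#' @param entry a `compound_entry`.
#' @param axis grid template, required when the entry is stored as Lorentzian
#'   signals (they are synthesized onto this axis).
#' @return list with `spectrum` (normalized `binned_spectrum`) and `scale`
#'   (the reporter height divided out).
#' @export
normalize_calibration <- function(entry, axis = NULL) {
  if (!is.null(entry$signals)) {
    if (is.null(axis))
      stop("`axis` template required for a Lorentzian-form entry",
           call. = FALSE)
    spec <- synthesize_spectrum(entry$signals, axis)
    scale <- .lorentzian_eval(entry$reporter_ppm, entry$signals,
                              axis$spectrometer_freq)
  } else {
    spec <- entry$spectrum
    scale <- intensity_at(spec, entry$reporter_ppm)
  }
  if (!is.finite(scale) || scale <= 0)
    stop(sprintf("library error: compound '%s' has non-positive height at its reporter position",
                 entry$compound_id), call. = FALSE)
  spec$intensities <- spec$intensities / scale
  list(spectrum = spec, scale = scale)
}

#' Reduce a normalized calibration spectrum to a calibration vector
#'
#' Element *i* is the normalized height at target position *i* (nearest bin);
#' negative baseline artifacts are clamped to zero so that all interference
#' elements are non-negative.
#'
#' @param normalized a reporter-normalized `binned_spectrum`.
#' @param target_positions numeric vector of ppm positions.
#' @return numeric vector, same length as `target_positions`, elements >= 0.
#' @export
calibration_vector <- function(normalized, target_positions)
  pmax(intensity_at(normalized, target_positions), 0)

# Normalized calibration height of an entry at given positions: closed form
# for Lorentzian entries (no grid aliasing), nearest-bin lookup for binned
# entries.  Clamped at 0.
.cal_height_norm <- function(entry, ppm, freq_mhz) {
  scale <- .cal_height_raw(entry, entry$reporter_ppm, freq_mhz)
  if (!is.finite(scale) || scale <= 0)
    stop(sprintf("library error: compound '%s' has non-positive height at its reporter position",
                 entry$compound_id), call. = FALSE)
  pmax(.cal_height_raw(entry, ppm, freq_mhz) / scale, 0)
}

#' Build the constant interference matrix
#'
#' Column *j* holds compound *j*'s reporter-normalized calibration heights
#' sampled at all *k* nominal target positions; the diagonal is exactly 1
#' because each compound's own target position is its reporter position.
#' This matrix models interferences under the assumption that all signal
#' positions and line widths are stable across spectra.
#'
#' @param library list of `compound_entry`s, aligned with `targets`.
#' @param targets a [target_table()], one row per compound, same order.
#' @param freq_mhz spectrometer frequency for Hz-to-ppm width conversion.
#' @return a k x k `interference_matrix` (base matrix with attributes
#'   `target_positions`, `variability`, `compound_class`).
#' @export
build_constant_matrix <- function(library, targets, freq_mhz = 600) {
  k <- length(library)
  if (nrow(targets) != k)
    stop("library and target table must have the same length/order",
         call. = FALSE)
  ids <- vapply(library, `[[`, "", "compound_id")
  if (!identical(ids, targets$compound_id))
    stop("library and target table compound order differ", call. = FALSE)
  if (anyDuplicated(round(targets$nominal_ppm, 4L)))
    warning("duplicate target positions: matrix rows may coincide")
  pos <- targets$nominal_ppm
  m <- matrix(0, k, k, dimnames = list(ids, ids))
  for (j in seq_len(k)) {
    rep_ppm <- library[[j]]$reporter_ppm
    if (abs(rep_ppm - pos[j]) > 1e-6)
      stop(sprintf("target position of '%s' (%.4f) does not match its reporter position (%.4f)",
                   ids[j], pos[j], rep_ppm), call. = FALSE)
    m[, j] <- .cal_height_norm(library[[j]], pos, freq_mhz)
    m[j, j] <- 1
  }
  if (rcond(m) < 1e-12)
    stop("interference matrix is numerically singular; revise target selection",
         call. = FALSE)
  structure(m,
            target_positions = pos,
            variability = vapply(library, `[[`, "", "variability"),
            compound_class = vapply(library, `[[`, "", "compound_class"),
            class = c("interference_matrix", "matrix", "array"))
}

#' Adapt the interference matrix to one spectrum
#'
#' For every variable compound whose signals were located in the spectrum, the
#' calibration spectrum is re-synthesized from the observed positions and line
#' widths (relative signal heights stay library-fixed so the reporter
#' normalization remains well defined), and the matrix is updated in two
#' places: the compound's \emph{column} is re-sampled at the current target
#' positions, and the \emph{row} of its (re-optimized) target position is
#' re-sampled for all compounds.  Everything else -- the constant portion --
#' is copied from the constant matrix unchanged, and the diagonal stays 1.
#'
#' A variable compound whose signals were not all found falls back to its
#' constant column/row; the affected compound ids are recorded in the
#' `fallback` attribute of the result.  Adaptation is also skipped -- keeping
#' the constant elements, which are then the better-characterized model --
#' when the observed geometry does not actually deviate from the library:
#' every apex within `pos_tol_ppm` of its nominal position and every line
#' width within `width_tol` (relative) of its library value.  This deadband
#' stops the per-spectrum matrix from chasing measurement noise in spectra
#' without real drift.
#'
#' @param constant_m the [build_constant_matrix()] result.
#' @param observations named list (by compound id) of observation lists as
#'   returned by [characterize_compound()], one element per variable compound,
#'   observation order matching the compound's library signal order.
#' @param library,targets as in [build_constant_matrix()].
#' @param freq_mhz spectrometer frequency (MHz).
#' @param pos_tol_ppm positional deadband (default half a standard 0.0002-ppm
#'   bin).
#' @param width_tol relative line-width deadband (default 0.05).
#' @return an `interference_matrix` with updated `target_positions` attribute.
#' @export
adapt_matrix <- function(constant_m, observations, library, targets,
                         freq_mhz = 600, pos_tol_ppm = 1e-4,
                         width_tol = 0.05) {
  ids <- vapply(library, `[[`, "", "compound_id")
  variability <- attr(constant_m, "variability")
  var_idx <- which(variability == "variable")
  if (length(var_idx) == 0L) return(constant_m)

  pos <- attr(constant_m, "target_positions")
  adapted <- library
  fallback <- character(0)
  live <- integer(0)
  for (v in var_idx) {
    id <- ids[v]
    obs <- observations[[id]]
    entry <- library[[v]]
    if (is.null(obs) || is.null(entry$signals) ||
        length(obs) != nrow(entry$signals) ||
        !all(vapply(obs, `[[`, TRUE, "found"))) {
      fallback <- c(fallback, id)
      next
    }
    sig <- entry$signals
    sig$center_ppm <- vapply(obs, `[[`, 0, "apex_ppm")
    sig$fwhm_hz <- vapply(obs, `[[`, 0, "fwhm_hz")
    deviates <-
      any(abs(sig$center_ppm - entry$signals$center_ppm) > pos_tol_ppm) ||
      any(abs(sig$fwhm_hz / entry$signals$fwhm_hz - 1) > width_tol)
    if (!deviates) next                   # constant elements are the model
    rep_sig <- which.min(abs(entry$signals$center_ppm - entry$reporter_ppm))
    ent2 <- entry
    ent2$signals <- sig
    ent2$reporter_ppm <- sig$center_ppm[rep_sig]
    adapted[[v]] <- ent2
    pos[v] <- ent2$reporter_ppm
    live <- c(live, v)
  }
  if (length(live) == 0L) {
    attr(constant_m, "fallback") <- fallback
    return(constant_m)
  }

  m <- constant_m
  attr(m, "target_positions") <- pos
  for (v in live) {                       # variable columns at current rows
    m[, v] <- .cal_height_norm(adapted[[v]], pos, freq_mhz)
    m[v, v] <- 1
  }
  for (v in live) {                       # re-optimized rows, all columns
    for (j in seq_along(adapted)) {
      if (j == v) next
      m[v, j] <- .cal_height_norm(adapted[[j]], pos[v], freq_mhz)
    }
  }
  attr(m, "fallback") <- fallback
  m
}

# ---- library I/O -----------------------------------------------------------

#' Read / write a compound library (JSON)
#'
#' The on-disk form is a JSON array with one object per compound:
#' `compound_id`, `class`, `variability`, `reporter_ppm`,
#' `response_factor_uM_per_unit`, and either `signals`
#' (array of `{center_ppm, fwhm_hz, rel_height}`) or `spectrum_path`
#' (resolved relative to the library file).
#'
#' @param path library file path.
#' @return list of `compound_entry`s.
#' @export
read_library <- function(path) {
  if (!file.exists(path))
    stop(sprintf("library file not found: %s", path), call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(e) {
    signals <- NULL
    spectrum <- NULL
    if (!is.null(e$signals)) {
      signals <- do.call(rbind, lapply(e$signals, function(s)
        data.frame(center_ppm = s$center_ppm, fwhm_hz = s$fwhm_hz,
                   rel_height = s$rel_height)))
    } else if (!is.null(e$spectrum_path)) {
      spectrum <- read_binned_spectrum(file.path(dirname(path),
                                                 e$spectrum_path))
    } else {
      stop(sprintf("library entry '%s' has neither signals nor spectrum_path",
                   e$compound_id), call. = FALSE)
    }
    compound_entry(e$compound_id, signals = signals, spectrum = spectrum,
                   reporter_ppm = e$reporter_ppm,
                   response_factor = e$response_factor_uM_per_unit %||%
                     NA_real_,
                   variability = e$variability %||% "constant",
                   compound_class = e$class %||% "metabolite")
  })
}

#' @rdname read_library
#' @param library list of `compound_entry`s (Lorentzian form only).
#' @export
write_library <- function(library, path) {
  out <- lapply(library, function(e) {
    if (is.null(e$signals))
      stop("only Lorentzian-form entries can be serialized", call. = FALSE)
    list(compound_id = e$compound_id, class = e$compound_class,
         variability = e$variability, reporter_ppm = e$reporter_ppm,
         response_factor_uM_per_unit = e$response_factor,
         signals = lapply(seq_len(nrow(e$signals)), function(i)
           list(center_ppm = e$signals$center_ppm[i],
                fwhm_hz = e$signals$fwhm_hz[i],
                rel_height = e$signals$rel_height[i])))
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Export an interference matrix as CSV
#'
#' Writes the matrix with a header row and leading column of compound ids so
#' matrices are comparable across runs.
#'
#' @param m an `interference_matrix`.
#' @param path output path.
#' @export
write_matrix_csv <- function(m, path) {
  df <- data.frame(compound_id = rownames(m), as.data.frame(unclass(m)[, ]),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
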
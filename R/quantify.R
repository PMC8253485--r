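#' Extract the target-signal vector from one spectrum
#'
#' Reads one target height per compound.  Constant targets are picked inside
#' their (small) search window; variable compounds reuse the reporter-signal
#' observation from the per-spectrum characterization step, so the target
#' position follows the observed drift.  When no peak is detected the height
#' falls back to the intensity read at the nominal position.
#'
#' @param spectrum a `binned_spectrum`.
#' @param targets a [target_table()].
#' @param library list of `compound_entry`s aligned with `targets` (used to
#'   locate each variable compound's reporter among its observations).
#' @param variable_observations named list (compound id ->
#'   [characterize_compound()] output) for the variable compounds; may be
#'   `NULL` when there are none.
#' @param noise noise level used for the detection decision during picking.
#' @param detection_multiplier detection threshold in noise units.
#' @return list with numeric vectors `y` (heights), `positions` (observed
#'   target positions, ppm), `position_bins` (0-based bins) and logical
#'   `found`.
#' @export
extract_targets <- function(spectrum, targets, library,
                            variable_observations = NULL, noise = 0,
                            detection_multiplier = 3) {
  k <- nrow(targets)
  y <- numeric(k); pos <- numeric(k); bin <- integer(k); found <- logical(k)
  for (i in seq_len(k)) {
    id <- targets$compound_id[i]
    obs <- NULL
    if (targets$variability[i] == "variable" &&
        !is.null(variable_observations[[id]])) {
      entry <- library[[i]]
      rep_sig <- which.min(abs(entry$signals$center_ppm - entry$reporter_ppm))
      obs <- variable_observations[[id]][[rep_sig]]
    }
    if (is.null(obs))
      obs <- pick_target_signal(spectrum, targets[i, ], noise,
                                detection_multiplier)
    y[i] <- obs$height
    pos[i] <- obs$apex_ppm
    bin[i] <- obs$apex_bin
    found[i] <- obs$found
  }
  list(y = stats::setNames(y, targets$compound_id),
       positions = stats::setNames(pos, targets$compound_id),
       position_bins = stats::setNames(bin, targets$compound_id),
       found = stats::setNames(found, targets$compound_id))
}

#' Solve the interference system for reporter heights
#'
#' Solves \eqn{\bar{y}_n = \bar{\bar{m}} \cdot \bar{x}_n} (constant matrix) or
#' \eqn{\bar{y}_n = \bar{\bar{m}}_n \cdot \bar{x}_n} (per-spectrum matrix) by
#' a direct dense solve.  Negative solutions are preserved as-is -- clipping
#' would break the linearity of the model -- and are expected to coincide
#' with below-detection reporters.
#'
#' @param m a k x k `interference_matrix` (or plain matrix).
#' @param y length-k numeric target vector.
#' @param condition_cap abort when the estimated condition number exceeds this
#'   (default 1e8): a silently unstable solve is worse than failure.
#' @return length-k numeric vector `x` of reporter heights.
#' @export
solve_reporters <- function(m, y, condition_cap = 1e8) {
  if (nrow(m) != ncol(m) || length(y) != nrow(m))
    stop("dimension mismatch between matrix and target vector", call. = FALSE)
  rc <- rcond(unclass(m))
  if (!is.finite(rc) || rc < 1 / condition_cap) {
    off <- abs(unclass(m)); diag(off) <- 0
    worst <- which(off == max(off), arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "interference matrix is ill-conditioned (rcond %.2e); largest off-diagonal coupling between '%s' and '%s'",
      rc, rownames(m)[worst[1L]] %||% worst[1L],
      colnames(m)[worst[2L]] %||% worst[2L]), call. = FALSE)
  }
  x <- solve(unclass(m), y)
  resid <- max(abs(unclass(m) %*% x - y))
  if (resid > 1e-9 * max(1, max(abs(y))))
    stop(sprintf("solver residual %.3e exceeds tolerance", resid),
         call. = FALSE)
  stats::setNames(as.numeric(x), rownames(m))
}

#' Relative interference
#'
#' \eqn{\Delta_i = (y_i - x_i)/y_i}: the fraction of a target signal's height
#' not attributable to the compound's own reporter.  Undefined (returned as
#' `NA`) where the target height is not positive.
#'
#' @param y target heights.
#' @param x reporter heights.
#' @return numeric vector of the same length.
#' @export
relative_interference <- function(y, x) {
  if (length(y) != length(x)) stop("length mismatch", call. = FALSE)
  ifelse(y > 0, (y - x) / y, NA_real_)
}

#' Convert reporter heights to concentrations
#'
#' Metabolite concentrations are `x * response_factor` (micromolar in the NMR
#' sample).  Non-metabolite entries (the EDTA species, the internal standard)
#' are modelled for interference correction only and get `NA`.
#'
#' @param x named reporter-height vector.
#' @param library list of `compound_entry`s, same order.
#' @return numeric vector of concentrations (uM), `NA` for non-metabolites.
#' @export
to_concentrations <- function(x, library) {
  vapply(seq_along(library), function(i) {
    e <- library[[i]]
    if (e$compound_class != "metabolite") return(NA_real_)
    if (!is.finite(e$response_factor) || e$response_factor <= 0)
      stop(sprintf("library error: metabolite '%s' lacks a response factor",
                   e$compound_id), call. = FALSE)
    x[i] * e$response_factor
  }, numeric(1))
}

# Split the modelled interference received by each compound into the part
# contributed by metabolites and the part contributed by non-metabolites.
.interference_parts <- function(m, x, y, classes) {
  k <- length(x)
  met <- numeric(k); nonmet <- numeric(k)
  is_met <- classes == "metabolite"
  mm <- unclass(m)
  for (i in seq_len(k)) {
    contrib <- mm[i, ] * x
    contrib[i] <- 0
    met[i] <- sum(contrib[is_met])
    nonmet[i] <- sum(contrib[!is_met])
  }
  list(delta_met = ifelse(y > 0, met / y, NA_real_),
       delta_nonmet = ifelse(y > 0, nonmet / y, NA_real_))
}

# Quantify one spectrum against a prepared constant matrix.  Shared by both
# modes; in constant mode (or with no variable compounds) the adapted matrix
# IS the constant matrix, so the improved mode with an empty variable set is
# arithmetically identical to constant mode.
.quantify_spectrum <- function(spectrum, library, targets, constant_m, mode,
                               noise_region, detection_multiplier,
                               condition_cap, freq_mhz) {
  noise <- estimate_noise(spectrum, noise_region)$level
  var_obs <- NULL
  if (mode == "improved") {
    var_idx <- which(targets$variability == "variable")
    var_obs <- list()
    for (v in var_idx) {
      entry <- library[[v]]
      guides <- target_table(
        compound_id = rep(entry$compound_id, nrow(entry$signals)),
        nominal_ppm = entry$signals$center_ppm,
        window_ppm = targets$window_ppm[v],
        variability = "variable")
      var_obs[[entry$compound_id]] <-
        characterize_compound(spectrum, guides, noise, detection_multiplier)
    }
  }
  m <- if (mode == "improved")
    adapt_matrix(constant_m, var_obs, library, targets, freq_mhz)
  else constant_m

  ext <- extract_targets(spectrum, targets, library, var_obs, noise,
                         detection_multiplier)
  x <- solve_reporters(m, ext$y, condition_cap)
  delta <- relative_interference(ext$y, x)
  parts <- .interference_parts(m, x, ext$y, attr(constant_m, "compound_class"))
  conc <- to_concentrations(x, library)
  data.frame(
    spectrum_id = spectrum$id,
    compound_id = targets$compound_id,
    compound_class = attr(constant_m, "compound_class"),
    y = as.numeric(ext$y),
    delta_y_ppm = as.numeric(ext$positions),
    position_bin = as.integer(ext$position_bins),
    x = as.numeric(x),
    delta = as.numeric(delta),
    delta_met = as.numeric(parts$delta_met),
    delta_nonmet = as.numeric(parts$delta_nonmet),
    conc_uM = as.numeric(conc),
    below_detection = as.numeric(x) <= detection_multiplier * noise,
    found = as.logical(ext$found),
    noise = noise,
    mode = mode,
    stringsAsFactors = FALSE)
}

#' Quantify a dataset of spectra
#'
#' The core computation.  In `"constant"` mode one interference matrix is
#' built from the library at the nominal target positions and reused for all
#' spectra.  In `"improved"` mode the signals of every variable compound are
#' located in each spectrum first, the matrix is adapted accordingly (see
#' [adapt_matrix()]), and the adapted system is solved per spectrum.
#'
#' @param spectra list of `binned_spectrum`s.
#' @param library list of `compound_entry`s.
#' @param targets a [target_table()] aligned with the library.
#' @param mode `"improved"` or `"constant"`.
#' @param noise_region length-2 ppm range used for the per-spectrum noise
#'   estimate.
#' @param detection_multiplier detection threshold in noise units (default 3).
#' @param condition_cap see [solve_reporters()].
#' @param strict when `TRUE`, a per-spectrum failure aborts the run; otherwise
#'   the spectrum is skipped and recorded in the `failures` attribute.
#' @param verbose log one line per spectrum.
#' @return a `data.frame` (class `quant_records`) with one row per spectrum x
#'   compound: `spectrum_id`, `compound_id`, `compound_class`, `y`,
#'   `delta_y_ppm`, `position_bin`, `x`, `delta`, `delta_met`,
#'   `delta_nonmet`, `conc_uM`, `below_detection`, `found`, `noise`, `mode`.
#' @export
quantify_dataset <- function(spectra, library, targets,
                             mode = c("improved", "constant"),
                             noise_region = c(10, 11),
                             detection_multiplier = 3,
                             condition_cap = 1e8,
                             strict = FALSE, verbose = FALSE) {
  mode <- match.arg(mode)
  freq_mhz <- spectra[[1L]]$spectrometer_freq
  constant_m <- build_constant_matrix(library, targets, freq_mhz)
  out <- vector("list", length(spectra))
  failures <- character(0)
  for (n in seq_along(spectra)) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(
      .quantify_spectrum(spectra[[n]], library, targets, constant_m, mode,
                         noise_region, detection_multiplier, condition_cap,
                         freq_mhz),
      error = function(e) e)
    if (inherits(res, "error")) {
      if (strict) stop(res)
      warning(sprintf("spectrum '%s' skipped: %s", spectra[[n]]$id,
                      conditionMessage(res)), call. = FALSE)
      failures <- c(failures, spectra[[n]]$id)
      next
    }
    out[[n]] <- res
    if (verbose)
      message(sprintf("[%s] %s: %d compounds in %.3f s", mode,
                      spectra[[n]]$id, nrow(targets),
                      proc.time()[["elapsed"]] - t0))
  }
  records <- do.call(rbind, out)
  rownames(records) <- NULL
  attr(records, "mode") <- mode
  attr(records, "failures") <- failures
  class(records) <- c("quant_records", "data.frame")
  records
}

#' Read / write quantification records as CSV
#'
#' @param records a `quant_records` data.frame.
#' @param path file path.
#' @export
write_quant_csv <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_quant_csv
#' @export
read_quant_csv <- function(path) {
  if (!file.exists(path))
    stop(sprintf("results file not found: %s", path), call. = FALSE)
  records <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(records) <- c("quant_records", "data.frame")
  records
}
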
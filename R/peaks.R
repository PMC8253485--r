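#' Estimate spectral noise from a signal-free region
#'
#' The noise level is the standard deviation of the intensities in a
#' user-chosen quiet region after removing the region's linear trend, the
#' usual convention for detection limits in 1D NMR.  The default region
#' (10--11 ppm) is empty in ultrafiltered plasma spectra.
#'
#' @param spectrum a `binned_spectrum`.
#' @param region length-2 numeric, (lo_ppm, hi_ppm); must cover at least 32
#'   bins.
#' @return list with elements `level` (SD after detrend) and `region`, class
#'   `noise_estimate`.
#' @export
estimate_noise <- function(spectrum, region = c(10, 11)) {
  sub <- slice_region(spectrum, region[1L], region[2L])
  n <- n_bins(sub)
  if (n < 32L)
    stop(sprintf("noise region [%g, %g] covers only %d bins (>= 32 required)",
                 region[1L], region[2L], n), call. = FALSE)
  y <- sub$intensities
  t <- seq_len(n) - (n + 1) / 2          # centred index; detrend y ~ a + b t
  b <- sum(t * y) / sum(t * t)
  res <- y - mean(y) - b * t
  structure(list(level = stats::sd(res), region = as.numeric(region[1:2])),
            class = "noise_estimate")
}

# Local maxima (strictly greater than nearest non-equal neighbours on both
# sides; plateaus resolve to the lowest bin index) among 0-based bins
# [b_lo, b_hi].  Neighbours outside the window but inside the spectrum count.
.local_maxima <- function(y, b_lo, b_hi) {
  n <- length(y)
  out <- integer(0)
  for (b in b_lo:b_hi) {
    i <- b + 1L                                   # 1-based
    if (i > 1L && y[i - 1L] == y[i]) next         # not the first bin of a run
    l <- i - 1L                                   # nearest non-equal left
    while (l >= 1L && y[l] == y[i]) l <- l - 1L
    if (l < 1L || y[l] >= y[i]) next
    r <- i + 1L                                   # nearest non-equal right
    while (r <= n && y[r] == y[i]) r <- r + 1L
    if (r > n || y[r] >= y[i]) next
    out <- c(out, b)
  }
  out
}

#' Full width at half maximum of a picked peak
#'
#' Scans outward from the apex until the intensity first drops to or below
#' half the apex height on each side, interpolating the crossing between the
#' bracketing bins.  Because the line shapes are modelled as Lorentzians, the
#' interpolation is performed on the reciprocal-intensity scale (1/I is linear
#' in the squared distance from the centre of a Lorentzian), which recovers
#' the width of an ideal on-grid Lorentzian to machine precision; an exact
#' half-height hit at a bin is taken as-is, so linear shapes with on-grid
#' crossings are also exact.  If the intensity starts rising again before
#' crossing (an overlapped shoulder) that side is abandoned and the other
#' side's width is doubled, flagged asymmetric.
#'
#' @param spectrum a `binned_spectrum`.
#' @param apex_bin 0-based bin index of a local maximum with positive height.
#' @param spectrometer_freq MHz; defaults to the spectrum's.
#' @return list with `fwhm_hz`, `fwhm_ppm` and logical `asymmetric`.
#' @export
estimate_fwhm <- function(spectrum, apex_bin,
                          spectrometer_freq = spectrum$spectrometer_freq) {
  y <- spectrum$intensities
  i0 <- apex_bin + 1L
  h <- y[i0]
  if (!is.finite(h) || h <= 0)
    stop("apex height must be positive", call. = FALSE)
  half <- h / 2

  scan_side <- function(step) {
    i <- i0
    vmin <- h
    repeat {
      j <- i + step
      if (j < 1L || j > length(y)) return(NA_real_)     # ran off the spectrum
      if (y[j] <= half) {
        if (y[j] == half) return(abs(j - i0))
        d1 <- abs(i - i0); d2 <- abs(j - i0)
        y1 <- y[i]; y2 <- y[j]
        if (y2 > 0) {
          # reciprocal-scale interpolation: 1/I linear in d^2 for a Lorentzian
          u1 <- 1 / y1; u2 <- 1 / y2; uh <- 1 / half
          d2sq <- d1^2 + (uh - u1) / (u2 - u1) * (d2^2 - d1^2)
          return(sqrt(d2sq))
        }
        return(d1 + (y1 - half) / (y1 - y2))            # fallback: linear
      }
      # shoulder: intensity rises significantly above the running minimum
      # before ever crossing half height (a small margin keeps single noisy
      # bins from aborting the scan)
      vmin <- min(vmin, y[j])
      if (y[j] > vmin + 0.1 * h && y[j] > y[i]) return(NA_real_)
      i <- j
    }
  }

  left <- scan_side(-1L)
  right <- scan_side(1L)
  asymmetric <- FALSE
  if (is.na(left) && is.na(right))
    stop("no half-height crossing found on either side of the apex",
         call. = FALSE)
  if (is.na(left)) { left <- right; asymmetric <- TRUE }
  if (is.na(right)) { right <- left; asymmetric <- TRUE }
  fwhm_ppm <- (left + right) * spectrum$bin_width
  list(fwhm_hz = ppm_to_hz(fwhm_ppm, spectrometer_freq),
       fwhm_ppm = fwhm_ppm, asymmetric = asymmetric)
}

#' Guided picking of one target signal
#'
#' Searches the window `nominal_ppm +/- window_ppm` for local maxima and
#' returns the most intense one (ties: nearest to the nominal position, then
#' lower ppm).  The signal counts as found when its apex height exceeds
#' `detection_multiplier * noise`.  When nothing is found the observation
#' falls back to the nominal position and the intensity read there, with
#' `found = FALSE`.
#'
#' A three-point parabolic sub-bin apex refinement is reported as
#' `apex_ppm_refined`, but `apex_ppm`/`apex_bin` stay on-grid: interference
#' matrices are sampled at bin centres.
#'
#' @param spectrum a `binned_spectrum`.
#' @param target one-row [target_table()] (or a list with `compound_id`,
#'   `nominal_ppm`, `window_ppm`).
#' @param noise noise level (a `noise_estimate` or a number); 0 disables the
#'   detection limit.
#' @param detection_multiplier detection threshold in noise units (default 3).
#' @return a `signal_observation`: list with `compound_id`, `apex_ppm`,
#'   `apex_ppm_refined`, `apex_bin`, `height`, `fwhm_hz`, `fwhm_asymmetric`,
#'   `found`.
#' @export
pick_target_signal <- function(spectrum, target, noise = 0,
                               detection_multiplier = 3) {
  if (inherits(noise, "noise_estimate")) noise <- noise$level
  nominal <- target$nominal_ppm
  win <- target$window_ppm
  if (nominal - win < spectrum$ppm_start - spectrum$bin_width / 2 ||
      nominal + win > ppm_end(spectrum) + spectrum$bin_width / 2)
    stop(sprintf("search window %.4f +/- %.4f ppm outside spectrum",
                 nominal, win), call. = FALSE)
  b_lo <- ppm_to_bin(spectrum, nominal - win)
  b_hi <- ppm_to_bin(spectrum, nominal + win)
  y <- spectrum$intensities
  cand <- .local_maxima(y, b_lo, b_hi)

  obs <- list(compound_id = as.character(target$compound_id),
              apex_ppm = nominal, apex_ppm_refined = nominal,
              apex_bin = ppm_to_bin(spectrum, nominal),
              height = intensity_at(spectrum, nominal),
              fwhm_hz = NA_real_, fwhm_asymmetric = NA,
              found = FALSE)
  class(obs) <- "signal_observation"
  if (length(cand) == 0L) return(obs)

  hts <- y[cand + 1L]
  best <- cand[hts == max(hts)]
  if (length(best) > 1L) {                      # exact height tie
    dist <- abs(bin_to_ppm(spectrum, best) - nominal)
    best <- best[dist == min(dist)]
    best <- best[1L]                            # still tied: lower ppm
  }
  height <- y[best + 1L]
  if (!(height > detection_multiplier * noise)) return(obs)

  obs$found <- TRUE
  obs$apex_bin <- best
  obs$apex_ppm <- bin_to_ppm(spectrum, best)
  obs$height <- height
  # parabolic refinement (vertex of the 3-point parabola)
  i <- best + 1L
  if (i > 1L && i < length(y)) {
    den <- y[i - 1L] - 2 * y[i] + y[i + 1L]
    if (den < 0) {
      off <- 0.5 * (y[i - 1L] - y[i + 1L]) / den
      obs$apex_ppm_refined <- obs$apex_ppm + off * spectrum$bin_width
    } else obs$apex_ppm_refined <- obs$apex_ppm
  } else obs$apex_ppm_refined <- obs$apex_ppm
  fw <- tryCatch(estimate_fwhm(spectrum, best), error = function(e) NULL)
  if (!is.null(fw)) {
    obs$fwhm_hz <- fw$fwhm_hz
    obs$fwhm_asymmetric <- fw$asymmetric
  }
  obs
}

#' @export
print.signal_observation <- function(x, ...) {
  cat(sprintf("<signal '%s': %s at %.4f ppm, height %.4g, FWHM %s Hz>\n",
              x$compound_id, if (x$found) "found" else "not found",
              x$apex_ppm, x$height,
              if (is.na(x$fwhm_hz)) "NA" else sprintf("%.3f", x$fwhm_hz)))
  invisible(x)
}

#' Characterize all signals of one compound in a spectrum
#'
#' Runs [pick_target_signal()] once per guide (one guide per expected signal
#' of the compound, e.g. the two singlets of free EDTA at 3.62 and 3.23 ppm)
#' and returns the observations in guide order.
#'
#' @param spectrum a `binned_spectrum`.
#' @param guides a [target_table()] with one row per expected signal.
#' @inheritParams pick_target_signal
#' @return list of `signal_observation`s.
#' @export
characterize_compound <- function(spectrum, guides, noise = 0,
                                  detection_multiplier = 3) {
  lapply(seq_len(nrow(guides)), function(i)
    pick_target_signal(spectrum, guides[i, ], noise, detection_multiplier))
}
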
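# Independent oracles and small fixture builders used across the suite.

# Dense linear solve by Gauss-Jordan elimination with partial pivoting --
# deliberately independent of base::solve / LAPACK, used to cross-check
# solve_reporters().
gauss_jordan_solve <- function(m, y) {
  a <- cbind(unclass(m), y)
  n <- nrow(a)
  for (col in seq_len(n)) {
    piv <- which.max(abs(a[col:n, col])) + col - 1L
    if (abs(a[piv, col]) < .Machine$double.eps)
      stop("singular matrix in oracle")
    if (piv != col) a[c(col, piv), ] <- a[c(piv, col), ]
    a[col, ] <- a[col, ] / a[col, col]
    for (r in seq_len(n)) {
      if (r != col && a[r, col] != 0)
        a[r, ] <- a[r, ] - a[r, col] * a[col, ]
    }
  }
  a[, n + 1L]
}

# Closed-form Lorentzian evaluated directly (independent of the package's
# internal evaluator).
lorentz_value <- function(ppm, center, fwhm_hz, height, freq = 600) {
  hw <- fwhm_hz / freq / 2
  height * hw^2 / ((ppm - center)^2 + hw^2)
}

# Blank axis template.
make_axis <- function(lo, hi, bw = 2e-4, freq = 600, id = "axis") {
  n <- round((hi - lo) / bw) + 1L
  binned_spectrum(lo, bw, numeric(n), freq, id)
}

# Brute-force positional-deviation oracle: smallest integer radius d such
# that at least `coverage` of the median-centred |deviations| are <= d.
brute_positional_deviation <- function(pos, coverage = 0.95) {
  med <- sort(pos)[floor((length(pos) + 1) / 2)]
  dev <- abs(pos - med)
  d <- 0L
  while (mean(dev <= d) < coverage) d <- d + 1L
  d
}

# Two-compound toy library: B's calibration spectrum leaks height 0.5 onto
# A's target position, nothing conversely.
two_compound_library <- function() {
  list(
    compound_entry("A", signals = lorentzian_signal(1.0, 1.5, 1),
                   reporter_ppm = 1.0, response_factor = 100),
    compound_entry("B",
                   signals = rbind(lorentzian_signal(2.0, 1.5, 1),
                                   lorentzian_signal(1.0, 1.5, 0.5)),
                   reporter_ppm = 2.0, response_factor = 50))
}

two_compound_targets <- function()
  target_table(c("A", "B"), c(1.0, 2.0), 2e-4)

# Noise-free quantification conditions for the EDTA-plasma preset: used by
# the exact-recovery and direction checks, which the contracts state for
# noiseless data.
preset_noiseless <- function(n, seed, zero_drift = FALSE) {
  cfg <- edta_plasma_preset(n, seed = seed)
  cfg$noise_sd <- 0
  cfg$constant_jitter_sd_bins <- 0
  if (zero_drift) {
    cfg$variable_shift_max_bins <- 0L
    cfg$variable_fwhm_range_hz <- NULL
  }
  cfg
}
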
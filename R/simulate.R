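#' Simulation configuration
#'
#' Describes a synthetic dataset: a Lorentzian-form compound library, planted
#' reporter heights drawn log-normally per compound, small integer-bin jitter
#' for constant compounds, large uniform integer-bin drift plus line-width
#' variation for variable compounds, and i.i.d. Gaussian baseline noise.
#'
#' @param library list of Lorentzian-form `compound_entry`s.
#' @param targets a [target_table()] aligned with the library.
#' @param ppm_start,n_bins,bin_width,spectrometer_freq axis definition.
#' @param x_median,x_cv per-compound median and coefficient of variation of
#'   the planted reporter height (log-normal; `cv = 0` plants the median
#'   deterministically).
#' @param constant_jitter_sd_bins SD of the Gaussian per-signal jitter of
#'   constant compounds, rounded to whole bins.
#' @param variable_shift_max_bins half-range of the uniform integer-bin drift
#'   of variable-compound signals.
#' @param variable_fwhm_range_hz length-2 range of the per-signal line width
#'   drawn for variable compounds (Hz).
#' @param noise_sd SD of the additive Gaussian bin noise.
#' @param noise_region signal-free ppm range reserved for noise estimation.
#' @param n_spectra number of spectra.
#' @param seed RNG seed; a fixed seed makes the dataset bit-reproducible.
#' @return a `simulation_config`.
#' @export
simulation_config <- function(library, targets, ppm_start, n_bins,
                              bin_width = 2e-4, spectrometer_freq = 600,
                              x_median, x_cv,
                              constant_jitter_sd_bins = 0,
                              variable_shift_max_bins = 0,
                              variable_fwhm_range_hz = NULL,
                              noise_sd = 0,
                              noise_region = c(10, 11),
                              n_spectra = 1, seed = 1) {
  k <- length(library)
  stopifnot(nrow(targets) == k, length(x_median) == k, length(x_cv) == k,
            n_spectra >= 1)
  if (constant_jitter_sd_bins < 0 || variable_shift_max_bins < 0 ||
      noise_sd < 0 || any(x_cv < 0))
    stop("spread parameters must be non-negative", call. = FALSE)
  structure(
    list(library = library, targets = targets, ppm_start = ppm_start,
         n_bins = as.integer(n_bins), bin_width = bin_width,
         spectrometer_freq = spectrometer_freq,
         x_median = as.numeric(x_median), x_cv = as.numeric(x_cv),
         constant_jitter_sd_bins = constant_jitter_sd_bins,
         variable_shift_max_bins = as.integer(variable_shift_max_bins),
         variable_fwhm_range_hz = variable_fwhm_range_hz,
         noise_sd = noise_sd, noise_region = as.numeric(noise_region),
         n_spectra = as.integer(n_spectra), seed = as.integer(seed)),
    class = "simulation_config")
}

# The toy plasma metabolite panel: positions in the crowded 1.3--4.1 ppm
# region, several of them inside the tails of the drifting free-EDTA singlets
# (3.62 / 3.23 ppm) or of the stable Ca/Mg complex signals.
.preset_metabolites <- function() {
  data.frame(
    compound_id = c("alanine", "lactate", "creatinine", "glucose", "glycine",
                    "histidine", "dimethylsulfone", "acetylcarnitine",
                    "carnitine", "ornithine"),
    ppm = c(1.480, 1.330, 3.040, 3.490, 3.565,
            3.145, 3.640, 3.600, 3.250, 3.190),
    conc_median_uM = c(350, 1500, 60, 4500, 250, 80, 8, 8, 40, 60),
    response_factor = c(350, 1000, 60, 3000, 250, 100, 10, 10, 50, 75),
    stringsAsFactors = FALSE)
}

#' EDTA-plasma-like simulation preset
#'
#' A ready-made configuration emulating finely binned (0.0002 ppm/bin, 600
#' MHz) spectra of ultrafiltered plasma collected with EDTA as the
#' anticoagulant: a toy metabolite panel with at most one-bin positional
#' jitter; two high-intensity free-EDTA singlets (3.62 and 3.23 ppm) that
#' drift up to +/-10 bins with line widths drawn from 1.0--2.2 Hz; stable
#' Ca-EDTA (3.13/2.55 ppm) and Mg-EDTA (2.69/3.21 ppm) complex signals; a
#' fixed TSP internal-standard singlet at 0 ppm; and additive Gaussian bin
#' noise.  The 4.0--4.2 ppm region is kept signal-free for noise estimation.
#'
#' @param n_spectra number of spectra.
#' @param seed RNG seed.
#' @param n_metabolites panel size; the first 10 are the named toy panel,
#'   larger values (up to 54) append generic singlets spaced over 0.9--2.2
#'   ppm to reproduce production-scale library dimensions.
#' @return a `simulation_config`.
#' @export
edta_plasma_preset <- function(n_spectra, seed = 1, n_metabolites = 10) {
  stopifnot(n_spectra >= 1, n_metabolites >= 1, n_metabolites <= 54)
  met <- .preset_metabolites()[seq_len(min(n_metabolites, 10L)), ]
  if (n_metabolites > 10L) {
    extra <- n_metabolites - 10L
    pos <- seq(0.90, by = 0.03, length.out = extra)
    met <- rbind(met, data.frame(
      compound_id = sprintf("metab%02d", 11:(10 + extra)),
      ppm = pos, conc_median_uM = 100, response_factor = 100))
  }
  lib <- lapply(seq_len(nrow(met)), function(i)
    compound_entry(met$compound_id[i],
                   signals = lorentzian_signal(met$ppm[i], 1.5, 1),
                   reporter_ppm = met$ppm[i],
                   response_factor = met$response_factor[i],
                   variability = "constant", compound_class = "metabolite"))
  lib <- c(lib, list(
    compound_entry("free_edta",
                   signals = lorentzian_signal(c(3.62, 3.23), c(1.5, 1.5),
                                               c(1, 0.85)),
                   reporter_ppm = 3.62, variability = "variable",
                   compound_class = "nonmetabolite"),
    compound_entry("ca_edta",
                   signals = lorentzian_signal(c(3.13, 2.55), c(1.6, 1.6),
                                               c(1, 0.9)),
                   reporter_ppm = 3.13, variability = "constant",
                   compound_class = "nonmetabolite"),
    compound_entry("mg_edta",
                   signals = lorentzian_signal(c(2.69, 3.21), c(1.6, 1.6),
                                               c(1, 0.9)),
                   reporter_ppm = 2.69, variability = "constant",
                   compound_class = "nonmetabolite"),
    compound_entry("tsp",
                   signals = lorentzian_signal(0.0, 1.1, 1),
                   reporter_ppm = 0.0, variability = "constant",
                   compound_class = "nonmetabolite")))
  bw <- 2e-4
  targets <- target_table(
    compound_id = vapply(lib, `[[`, "", "compound_id"),
    nominal_ppm = vapply(lib, `[[`, 0, "reporter_ppm"),
    window_ppm = ifelse(vapply(lib, `[[`, "", "variability") == "variable",
                        15 * bw, 1 * bw),
    variability = vapply(lib, `[[`, "", "variability"))
  k <- length(lib)
  x_median <- c(met$conc_median_uM / met$response_factor, 50, 30, 25, 10)
  x_cv <- c(rep(0.3, nrow(met)), 0.5, 0.15, 0.15, 0)
  simulation_config(
    library = lib, targets = targets,
    ppm_start = -0.05, n_bins = 21501L, bin_width = bw,
    spectrometer_freq = 600,
    x_median = x_median, x_cv = x_cv,
    constant_jitter_sd_bins = 0.4,
    variable_shift_max_bins = 10,
    variable_fwhm_range_hz = c(1.0, 2.2),
    noise_sd = 0.005, noise_region = c(4.02, 4.18),
    n_spectra = n_spectra, seed = seed)
}

#' Simulate a dataset of binned spectra with known ground truth
#'
#' Each spectrum is the sum over compounds of the planted reporter height
#' times the compound's reporter-normalized Lorentzian shape (evaluated with
#' the drawn per-spectrum geometry), plus Gaussian bin noise.  Randomness is
#' drawn from a single RNG stream keyed by `config$seed` in a fixed order --
#' spectrum-major, then compound in library order (height, per-signal shift,
#' per-signal width for variable compounds), then the noise vector -- so a
#' given seed reproduces the dataset bit-for-bit.
#'
#' @param config a `simulation_config`.
#' @return list with `spectra` (list of `binned_spectrum`), `truth`
#'   (data.frame: spectrum_id, compound_id, x_true, conc_true_uM,
#'   reporter_shift_bins, reporter_fwhm_hz), `library`, `targets`, `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  lib <- config$library
  k <- length(lib)
  freq <- config$spectrometer_freq
  axis_ppm <- config$ppm_start + (seq_len(config$n_bins) - 1) * config$bin_width
  set.seed(config$seed)

  sdlog <- sqrt(log(1 + config$x_cv^2))
  spectra <- vector("list", config$n_spectra)
  truth <- vector("list", config$n_spectra)
  for (n in seq_len(config$n_spectra)) {
    id <- sprintf("sim%04d", n)
    y <- numeric(config$n_bins)
    x_true <- numeric(k)
    rep_shift <- integer(k); rep_fwhm <- numeric(k)
    for (j in seq_len(k)) {
      e <- lib[[j]]
      x <- if (config$x_cv[j] > 0)
        stats::rlnorm(1, meanlog = log(config$x_median[j]),
                      sdlog = sdlog[j])
      else config$x_median[j]
      sig <- e$signals
      ns <- nrow(sig)
      if (e$variability == "variable") {
        shift <- sample.int(2L * config$variable_shift_max_bins + 1L, ns,
                            replace = TRUE) - config$variable_shift_max_bins - 1L
        fr <- config$variable_fwhm_range_hz
        fw <- if (is.null(fr)) sig$fwhm_hz else stats::runif(ns, fr[1], fr[2])
      } else {
        shift <- as.integer(round(stats::rnorm(ns, 0,
                                               config$constant_jitter_sd_bins)))
        fw <- sig$fwhm_hz
      }
      sig$center_ppm <- sig$center_ppm + shift * config$bin_width
      sig$fwhm_hz <- fw
      # normalize the drawn geometry so that the planted x is exactly the
      # height of the compound's contribution at its (shifted) reporter
      rep_sig <- which.min(abs(e$signals$center_ppm - e$reporter_ppm))
      rep_ppm_n <- sig$center_ppm[rep_sig]
      norm <- .lorentzian_eval(rep_ppm_n, sig, freq)
      y <- y + (x / norm) * .lorentzian_eval(axis_ppm, sig, freq)
      x_true[j] <- x
      rep_shift[j] <- shift[rep_sig]
      rep_fwhm[j] <- fw[rep_sig]
    }
    if (config$noise_sd > 0)
      y <- y + stats::rnorm(config$n_bins, 0, config$noise_sd)
    spectra[[n]] <- binned_spectrum(config$ppm_start, config$bin_width, y,
                                    freq, id)
    rf <- vapply(lib, `[[`, 0, "response_factor")
    truth[[n]] <- data.frame(
      spectrum_id = id,
      compound_id = vapply(lib, `[[`, "", "compound_id"),
      compound_class = vapply(lib, `[[`, "", "compound_class"),
      x_true = x_true,
      conc_true_uM = ifelse(vapply(lib, `[[`, "", "compound_class") ==
                              "metabolite", x_true * rf, NA_real_),
      reporter_shift_bins = rep_shift,
      reporter_fwhm_hz = rep_fwhm,
      stringsAsFactors = FALSE)
  }
  list(spectra = spectra, truth = do.call(rbind, truth),
       library = lib, targets = config$targets, config = config)
}

#' Write a simulated dataset to a directory
#'
#' Spectra go to `<dir>/spectra/*.csv` in the two-column dialect, the ground
#' truth to `ground_truth.csv`, and the generated library and target table to
#' `library.json` / `targets.tsv`.
#'
#' @param sim a [simulate_dataset()] result.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  spec_dir <- file.path(dir, "spectra")
  dir.create(spec_dir, recursive = TRUE, showWarnings = FALSE)
  for (s in sim$spectra)
    write_binned_spectrum(s, file.path(spec_dir, paste0(s$id, ".csv")))
  utils::write.csv(sim$truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  write_library(sim$library, file.path(dir, "library.json"))
  write_targets(sim$targets, file.path(dir, "targets.tsv"))
  invisible(dir)
}
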
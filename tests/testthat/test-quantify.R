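test_that("solve_reporters solves the interference system exactly", {
  # identity: x = y
  y <- c(2, 3, 5)
  expect_equal(solve_reporters(diag(3), y), y, ignore_attr = TRUE)

  # hand back-substitution: m = [[1, .5], [0, 1]], y = (1.5, 1) -> x = (1, 1)
  m <- matrix(c(1, 0, 0.5, 1), 2, 2)
  expect_equal(solve_reporters(m, c(1.5, 1)), c(1, 1), ignore_attr = TRUE)

  # forward-multiplication oracle on a random diagonally dominant system
  set.seed(5)
  k <- 6
  m6 <- matrix(stats::runif(k * k, 0, 0.9 / k), k, k); diag(m6) <- 1
  x_true <- stats::runif(k, 0, 10)
  x_hat <- solve_reporters(m6, drop(m6 %*% x_true))
  expect_lt(max(abs(x_hat - x_true)) / max(x_true), 1e-10)

  # an (almost) singular system aborts with a diagnostic
  bad <- matrix(c(1, 1, 1, 1 + 1e-12), 2, 2,
                dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(solve_reporters(bad, c(1, 1)), "ill-conditioned")
  expect_error(solve_reporters(diag(3), c(1, 2)), "dimension")
})

test_that("relative interference is (y - x)/y with undefined zero-height targets", {
  expect_equal(relative_interference(c(1, 1.5), c(1, 1)), c(0, 1 / 3))
  expect_true(is.na(relative_interference(0, 1)))
  expect_equal(relative_interference(2, 3), -0.5)  # negative interference kept
})

test_that("concentrations apply response factors to metabolites only", {
  lib <- list(
    compound_entry("met", signals = lorentzian_signal(1, 1.5, 1),
                   reporter_ppm = 1, response_factor = 50),
    compound_entry("edta", signals = lorentzian_signal(2, 1.5, 1),
                   reporter_ppm = 2, compound_class = "nonmetabolite"))
  conc <- to_concentrations(c(2, 3), lib)
  expect_equal(conc, c(100, NA_real_))
  expect_equal(to_concentrations(c(0, 0), lib)[1], 0)

  lib_bad <- lib
  lib_bad[[1]]$response_factor <- NA_real_
  expect_error(to_concentrations(c(1, 1), lib_bad), "response factor")
})

test_that("target extraction reads one height per compound at the observed position", {
  cfg <- preset_noiseless(1, seed = 3, zero_drift = TRUE)
  sim <- simulate_dataset(cfg)
  ext <- extract_targets(sim$spectra[[1]], sim$targets, sim$library)
  expect_identical(length(ext$y), nrow(sim$targets))
  expect_identical(names(ext$y), sim$targets$compound_id)
  # an isolated compound's target height is its planted reporter height
  tr <- sim$truth
  expect_equal(ext$y[["tsp"]],
               tr$x_true[tr$compound_id == "tsp"], tolerance = 1e-5)
  # zero spectrum: fallback to nominal positions, zero heights
  zero <- sim$spectra[[1]]
  zero$intensities <- numeric(n_bins(zero))
  ext0 <- extract_targets(zero, sim$targets, sim$library)
  expect_identical(unname(ext0$y), rep(0, nrow(sim$targets)))
  expect_equal(unname(ext0$positions), sim$targets$nominal_ppm)
})

test_that("noiseless simulated mixtures are recovered essentially exactly", {
  cfg <- preset_noiseless(6, seed = 17, zero_drift = TRUE)
  sim <- simulate_dataset(cfg)
  for (mode in c("constant", "improved")) {
    rec <- quantify_dataset(sim$spectra, sim$library, sim$targets,
                            mode = mode, noise_region = cfg$noise_region)
    m <- merge(rec, sim$truth, by = c("spectrum_id", "compound_id"))
    expect_lt(max(abs(m$x - m$x_true) / m$x_true), 1e-8)
    met <- m[m$compound_class.x == "metabolite", ]
    expect_lt(max(abs(met$conc_uM - met$conc_true_uM) / met$conc_true_uM),
              1e-8)
  }
})

test_that("improved mode with no variable compounds equals constant mode bit for bit", {
  cfg <- edta_plasma_preset(4, seed = 9)
  sim <- simulate_dataset(cfg)
  lib <- sim$library
  tt <- sim$targets
  # freeze every compound: the variable set becomes empty
  for (i in seq_along(lib)) lib[[i]]$variability <- "constant"
  tt$variability <- "constant"
  rec_c <- quantify_dataset(sim$spectra, lib, tt, mode = "constant",
                            noise_region = cfg$noise_region)
  rec_i <- quantify_dataset(sim$spectra, lib, tt, mode = "improved",
                            noise_region = cfg$noise_region)
  rec_i$mode <- rec_c$mode <- NULL
  strip <- function(r) {
    attr(r, "mode") <- NULL
    as.data.frame(r)
  }
  expect_identical(strip(rec_i), strip(rec_c))
})

test_that("a positive interference grows the interfered metabolite's delta monotonically", {
  # fixed geometry, increasing interferer height: delta of the interfered
  # compound must never decrease (noiseless)
  lib <- two_compound_library()
  tt <- two_compound_targets()
  m <- build_constant_matrix(lib, tt)
  deltas <- vapply(c(0.5, 1, 2, 4, 8), function(xb) {
    y <- drop(unclass(m) %*% c(1, xb))
    x <- solve_reporters(m, y)
    relative_interference(y, x)[1]
  }, numeric(1))
  expect_true(all(diff(deltas) >= 0))
})

test_that("ignoring a shifted interferer overestimates the affected metabolite", {
  # the interferer's tail adds positive height at the metabolite target; a
  # constant-mode quantification that knows nothing about the interferer
  # attributes that height to the metabolite, so x_constant >= x_improved
  cfg <- preset_noiseless(4, seed = 23)
  sim <- simulate_dataset(cfg)
  met_idx <- which(vapply(sim$library, `[[`, "", "compound_class") ==
                     "metabolite")
  rec_c <- quantify_dataset(sim$spectra, sim$library[met_idx],
                            sim$targets[met_idx, ], mode = "constant",
                            noise_region = cfg$noise_region)
  rec_i <- quantify_dataset(sim$spectra, sim$library, sim$targets,
                            mode = "improved",
                            noise_region = cfg$noise_region)
  for (id in c("dimethylsulfone", "acetylcarnitine", "carnitine")) {
    xc <- rec_c$x[rec_c$compound_id == id]
    xi <- rec_i$x[rec_i$compound_id == id]
    expect_true(all(xc >= xi))
  }
})

test_that("per-spectrum failures are skipped unless strict", {
  cfg <- preset_noiseless(2, seed = 31, zero_drift = TRUE)
  sim <- simulate_dataset(cfg)
  broken <- sim$spectra
  broken[[2]] <- binned_spectrum(3.0, 2e-4, numeric(100), id = "short")
  expect_warning(
    rec <- quantify_dataset(broken, sim$library, sim$targets,
                            mode = "constant",
                            noise_region = cfg$noise_region),
    "skipped")
  expect_identical(attr(rec, "failures"), "short")
  expect_identical(unique(rec$spectrum_id), sim$spectra[[1]]$id)
  expect_error(
    suppressWarnings(
      quantify_dataset(broken, sim$library, sim$targets, mode = "constant",
                       noise_region = cfg$noise_region, strict = TRUE)))
})

test_that("quantification records round-trip through CSV", {
  cfg <- preset_noiseless(1, seed = 2, zero_drift = TRUE)
  sim <- simulate_dataset(cfg)
  rec <- quantify_dataset(sim$spectra, sim$library, sim$targets,
                          mode = "improved", noise_region = cfg$noise_region)
  path <- withr::local_tempfile(fileext = ".csv")
  write_quant_csv(rec, path)
  back <- read_quant_csv(path)
  expect_identical(nrow(back), nrow(rec))
  expect_equal(back$x, rec$x, tolerance = 1e-12)
  expect_identical(back$mode, rec$mode)
})
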
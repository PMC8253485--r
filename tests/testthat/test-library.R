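test_that("Lorentzian synthesis matches the closed form at apex and half height", {
  axis <- make_axis(3.0, 3.2)
  sp <- synthesize_spectrum(lorentzian_signal(3.1, 1.2, 10), axis)
  # 1.2 Hz at 600 MHz = 0.0020 ppm FWHM = 10 bins; apex and half-height
  # positions sit exactly on bins
  expect_equal(intensity_at(sp, 3.1), 10, tolerance = 1e-12)
  expect_equal(intensity_at(sp, 3.1 + 0.001), 5, tolerance = 1e-12)
  expect_equal(intensity_at(sp, 3.1 - 0.001), 5, tolerance = 1e-12)

  expect_identical(synthesize_spectrum(NULL, axis)$intensities,
                   numeric(n_bins(axis)))
  expect_error(synthesize_spectrum(lorentzian_signal(5, 1.5, 1), axis),
               "outside")
})

test_that("two well-separated unit Lorentzians only perturb each other by their tails", {
  axis <- make_axis(3.0, 3.4)
  w_ppm <- hz_to_ppm(1.5, 600)
  sep <- 10 * w_ppm
  sp <- synthesize_spectrum(
    rbind(lorentzian_signal(3.15, 1.5, 1),
          lorentzian_signal(3.15 + sep, 1.5, 1)), axis)
  tail_exact <- lorentz_value(3.15, 3.15 + sep, 1.5, 1)
  for (pos in c(3.15, 3.15 + sep)) {
    expect_equal(intensity_at(sp, pos), 1 + tail_exact, tolerance = 1e-6)
    expect_lte(abs(intensity_at(sp, pos) - 1), 0.011)
  }
})

test_that("calibration normalization fixes the reporter height at exactly 1", {
  axis <- make_axis(0.8, 2.2)
  entry <- compound_entry("A", signals = lorentzian_signal(1.0, 1.5, 250),
                          reporter_ppm = 1.0, response_factor = 10)
  norm <- normalize_calibration(entry, axis)
  expect_equal(norm$scale, 250, tolerance = 1e-12)
  expect_equal(intensity_at(norm$spectrum, 1.0), 1, tolerance = 1e-12)

  # idempotence: normalizing an already-normalized spectrum changes nothing
  entry2 <- compound_entry("A", spectrum = norm$spectrum, reporter_ppm = 1.0,
                           response_factor = 10)
  norm2 <- normalize_calibration(entry2)
  expect_equal(norm2$scale, 1, tolerance = 1e-12)
  expect_equal(norm2$spectrum$intensities, norm$spectrum$intensities)

  zero <- compound_entry("Z", spectrum = binned_spectrum(0.8, 2e-4,
                                                         numeric(100)),
                         reporter_ppm = 0.81, response_factor = 1)
  expect_error(normalize_calibration(zero), "library error")
})

test_that("calibration vectors sample normalized heights, clamped at zero", {
  axis <- make_axis(0.8, 2.2)
  norm <- normalize_calibration(
    compound_entry("A", signals = lorentzian_signal(1.0, 1.5, 4),
                   reporter_ppm = 1.0, response_factor = 1), axis)$spectrum
  # isolated signal: unit basis vector at its own position
  v <- calibration_vector(norm, c(1.0, 1.8, 2.1))
  expect_equal(v[1], 1, tolerance = 1e-12)
  expect_lt(max(v[2:3]), 1e-4)

  # direct lookup oracle at an arbitrary position
  p <- 1.0012
  expect_equal(calibration_vector(norm, p),
               lorentz_value(bin_to_ppm(norm, ppm_to_bin(norm, p)),
                             1.0, 1.5, 1),
               tolerance = 1e-9)

  # negative baseline artifacts clamp to zero
  dirty <- binned_spectrum(0.8, 2e-4, c(rep(-0.2, 50), 1, rep(0, 49)))
  expect_identical(calibration_vector(dirty, 0.802), 0)
})

test_that("the constant matrix is the column-wise calibration of the library", {
  lib <- list(
    compound_entry("A", signals = lorentzian_signal(1.0, 1.5, 1),
                   reporter_ppm = 1.0, response_factor = 1),
    compound_entry("B", signals = lorentzian_signal(3.0, 1.5, 1),
                   reporter_ppm = 3.0, response_factor = 1))
  tt <- target_table(c("A", "B"), c(1.0, 3.0), 2e-4)
  m <- build_constant_matrix(lib, tt)
  expect_equal(unclass(m), diag(2), ignore_attr = TRUE, tolerance = 1e-5)

  m2 <- build_constant_matrix(two_compound_library(), two_compound_targets())
  expect_equal(m2["A", "B"], 0.5, tolerance = 1e-5)
  expect_lt(abs(m2["B", "A"] - lorentz_value(2.0, 1.0, 1.5, 1)), 1e-12)
  expect_identical(diag(unclass(m2)), c(A = 1, B = 1))
  expect_true(all(unclass(m2) >= 0))

  # production-scale shape: 54 metabolites + 3 EDTA species + standard
  cfg <- edta_plasma_preset(1, seed = 1, n_metabolites = 54)
  m3 <- build_constant_matrix(cfg$library, cfg$targets)
  expect_identical(dim(m3), c(58L, 58L))
})

test_that("calibration sampling agrees with the closed form at target positions", {
  # Lorentzian-form entries are sampled exactly; a binned version of the same
  # compound agrees to within the bin-centre discretization
  axis <- make_axis(3.0, 3.4)
  sig <- rbind(lorentzian_signal(3.1, 1.5, 2),
               lorentzian_signal(3.3, 1.5, 1))
  entry_l <- compound_entry("L", signals = sig, reporter_ppm = 3.1,
                            response_factor = 1)
  entry_b <- compound_entry("L", spectrum = synthesize_spectrum(sig, axis),
                            reporter_ppm = 3.1, response_factor = 1)
  pos <- c(3.1, 3.1501, 3.3)
  expected <- (lorentz_value(pos, 3.1, 1.5, 2) +
                 lorentz_value(pos, 3.3, 1.5, 1)) / 2
  v_l <- calibration_vector(normalize_calibration(entry_l, axis)$spectrum, pos)
  v_b <- calibration_vector(normalize_calibration(entry_b)$spectrum, pos)
  expect_equal(v_l, expected, tolerance = 0.005)
  expect_equal(v_b, expected, tolerance = 0.005)
})

test_that("matrix adaptation: identity without deviation, updated column/row with it", {
  cfg <- edta_plasma_preset(1, seed = 1)
  lib <- cfg$library; tt <- cfg$targets
  m0 <- build_constant_matrix(lib, tt)
  v <- which(tt$variability == "variable")
  entry <- lib[[v]]

  mk_obs <- function(centers, fwhms) {
    lapply(seq_along(centers), function(i)
      structure(list(compound_id = entry$compound_id,
                     apex_ppm = centers[i], apex_bin = 0L,
                     height = 1, fwhm_hz = fwhms[i], found = TRUE),
                class = "signal_observation"))
  }

  # observations at library values -> bit-identical matrix
  obs0 <- list(free_edta = mk_obs(entry$signals$center_ppm,
                                  entry$signals$fwhm_hz))
  expect_identical(unclass(adapt_matrix(m0, obs0, lib, tt))[, ],
                   unclass(m0)[, ])

  # a +10-bin shift moves the interference element off nearby targets:
  # the Lorentzian tail decays with distance, so elements for metabolites
  # on the far side strictly decrease
  bw <- 2e-4
  obs1 <- list(free_edta = mk_obs(entry$signals$center_ppm + 10 * bw,
                                  entry$signals$fwhm_hz))
  m1 <- adapt_matrix(m0, obs1, lib, tt)
  i_acar <- which(tt$compound_id == "acetylcarnitine")  # below 3.62
  expect_lt(m1[i_acar, v], m0[i_acar, v])
  # constant portion untouched, diagonal still 1
  keep <- setdiff(seq_len(nrow(m0)), v)
  expect_identical(unclass(m1)[keep, keep], unclass(m0)[keep, keep])
  expect_identical(unname(diag(unclass(m1))), rep(1, nrow(m1)))
  # target position of the variable compound followed the observation
  expect_equal(attr(m1, "target_positions")[v],
               entry$reporter_ppm + 10 * bw)

  # missing signals -> constant fallback, flagged
  obs_miss <- obs0
  obs_miss$free_edta[[1]]$found <- FALSE
  m2 <- adapt_matrix(m0, obs_miss, lib, tt)
  expect_identical(unclass(m2)[, ], unclass(m0)[, ])
  expect_identical(attr(m2, "fallback"), "free_edta")
})

test_that("libraries round-trip through JSON", {
  lib <- two_compound_library()
  path <- withr::local_tempfile(fileext = ".json")
  write_library(lib, path)
  back <- read_library(path)
  expect_identical(length(back), 2L)
  expect_equal(back[[2]]$signals, lib[[2]]$signals)
  expect_identical(back[[1]]$compound_id, "A")
  expect_identical(back[[1]]$variability, "constant")
  expect_equal(back[[2]]$response_factor, 50)
})
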
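test_that("generation is a pure function of the config, seed included", {
  cfg <- synthetic_config(n_samples = 12, n_wavelengths = 40, seed = 7)
  a <- generate_spectra(cfg)
  b <- generate_spectra(cfg)
  expect_identical(a$spectra$absorbance, b$spectra$absorbance)
  expect_identical(a$truth$ssc_true, b$truth$ssc_true)
  cfg8 <- synthetic_config(n_samples = 12, n_wavelengths = 40, seed = 8)
  c <- generate_spectra(cfg8)
  expect_false(identical(a$spectra$absorbance, c$spectra$absorbance))
})

test_that("disabling all corruption returns the clean spectra exactly", {
  cfg <- synthetic_config(n_samples = 8, n_wavelengths = 30,
                          scatter_slope_sd = 0, scatter_offset_sd = 0,
                          baseline_amplitude = 0, noise_sd = 0, seed = 3)
  out <- generate_spectra(cfg)
  expect_identical(out$spectra$absorbance, out$truth$clean_spectra)
})

test_that("stored draws reconstruct the emitted absorbance bit-exactly", {
  out <- generate_spectra(synthetic_config(n_samples = 10, n_wavelengths = 50,
                                           seed = 11))
  tr <- out$truth
  rebuilt <- tr$scatter_params$offset +
    (1 + tr$scatter_params$slope) * tr$clean_spectra +
    tr$baseline + tr$noise
  expect_identical(rebuilt, out$spectra$absorbance)
})

test_that("SSC draws honour the truncated-normal spec", {
  cfg <- synthetic_config(seed = 5)   # n = 160, mean 13.42, sd 1.28
  ssc <- generate_spectra(cfg)$spectra$ssc
  expect_true(all(ssc >= 10.81 & ssc <= 17.13))
  se <- 1.28 / sqrt(160)
  expect_lt(abs(mean(ssc) - 13.42), 3 * se)
})

test_that("informative windows are the analyte band supports", {
  cfg <- synthetic_config(n_samples = 8, n_wavelengths = 100, seed = 1)
  out <- generate_spectra(cfg)
  bands <- cfg$analyte_bands
  expect_equal(out$truth$informative_windows[, "low"], bands$center - 3 * bands$width)
  expect_equal(out$truth$informative_windows[, "high"], bands$center + 3 * bands$width)
  idx <- informative_indices(out$truth, out$spectra$wavenumbers)
  wn <- out$spectra$wavenumbers[idx]
  expect_true(all(vapply(wn, function(v)
    any(v >= out$truth$informative_windows[, "low"] &
        v <= out$truth$informative_windows[, "high"]), logical(1))))
})

test_that("clean informative columns carry the SSC signal and null columns do not", {
  # interferent bands live > 50 band-widths from every analyte window, so
  # analyte tails underflow there and the interferent columns' variance is
  # purely the SSC-independent amplitude jitter
  cfg <- synthetic_config(n_samples = 40, n_wavelengths = 120,
                          analyte_bands = data.frame(
                            center = c(4400, 5800, 8300), width = 40,
                            intensity = c(0.012, 0.008, 0.004)),
                          interferent_bands = data.frame(
                            center = c(9500, 9800), width = 20,
                            intensity = 0.5, variation = 0.5),
                          scatter_slope_sd = 0, scatter_offset_sd = 0,
                          baseline_amplitude = 0, noise_sd = 0, seed = 9)
  out <- generate_spectra(cfg)
  idx <- informative_indices(out$truth, out$spectra$wavenumbers)
  x_in <- out$truth$clean_spectra[, idx, drop = FALSE]
  fit_in <- lm.fit(cbind(1, x_in), out$truth$ssc_true)
  expect_lt(sqrt(mean(fit_in$residuals^2)), 1e-8)
  wn <- out$spectra$wavenumbers
  null_idx <- which(wn > 9450 & wn < 9850)
  x_null <- out$truth$clean_spectra[, null_idx, drop = FALSE]
  x_null <- x_null[, apply(x_null, 2, sd) > 0, drop = FALSE]
  fit_null <- lm.fit(cbind(1, x_null), out$truth$ssc_true)
  r2_null <- 1 - sum(fit_null$residuals^2) /
    sum((out$truth$ssc_true - mean(out$truth$ssc_true))^2)
  expect_lt(r2_null, 0.5)
})

test_that("invalid configs are rejected with the offending field named", {
  expect_error(synthetic_config(n_samples = 2), "n_samples")
  expect_error(synthetic_config(n_wavelengths = 4), "n_wavelengths")
  expect_error(synthetic_config(wavenumber_range = c(9000, 4000)), "wavenumber_range")
  expect_error(synthetic_config(ssc_bounds = c(14, 17)), "ssc_mean")
  expect_error(synthetic_config(ssc_sd = -1), "ssc_sd")
  expect_error(synthetic_config(analyte_bands = data.frame(
    center = 20000, width = 50, intensity = 1)), "analyte_bands")
  expect_error(synthetic_config(analyte_bands = default_analyte_bands()[0, ]),
               "analyte_bands")
})

test_that("benchmark preset marks exactly ten informative columns", {
  out <- generate_spectra(benchmark_config(seed = 1))
  idx <- informative_indices(out$truth, out$spectra$wavenumbers)
  expect_length(idx, 10)
  expect_equal(n_wavelengths(out$spectra), 200)
})
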
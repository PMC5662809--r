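make_set <- function(x, wn = seq(4000, by = 100, length.out = ncol(x))) {
  spectra_set(x, wn)
}

test_that("SNV centres and scales each spectrum (n-1 denominator)", {
  s <- make_set(rbind(c(1, 2, 3), c(10, 20, 60)))
  fp <- fit_preprocessor(preprocess_spec(step_snv()), s)
  out <- transform_spectra(fp, s)$absorbance
  expect_equal(out[1, ], c(-1, 0, 1))
  expect_equal(rowMeans(out), c(0, 0), tolerance = 1e-10)
  expect_equal(apply(out, 1, sd), c(1, 1), tolerance = 1e-10)
})

test_that("mean normalization divides by the row mean", {
  s <- make_set(matrix(c(2, 4, 6), 1))
  fp <- fit_preprocessor(preprocess_spec(step_meannorm()), s)
  expect_equal(transform_spectra(fp, s)$absorbance[1, ], c(0.5, 1.0, 1.5))
})

test_that("MSC with a known reference inverts an affine distortion exactly", {
  r <- c(1, 2, 3)
  s <- make_set(matrix(2 * r + 1, 1))          # a = 1, b = 2
  fp <- fit_preprocessor(preprocess_spec(step_msc(reference = r)), s)
  expect_equal(transform_spectra(fp, s)$absorbance[1, ], r, tolerance = 1e-12)
})

test_that("MSC reference is the calibration mean and is reused on new data", {
  set.seed(1)
  base <- sin(seq(0, 3, length.out = 25)) + 2
  cal <- make_set(t(sapply(1:6, function(i) 0.2 * i + (0.8 + 0.1 * i) * base)))
  fp <- fit_preprocessor(preprocess_spec(step_msc()), cal)
  expect_equal(fp$fitted[[1]]$reference, colMeans(cal$absorbance))
  # identical distortions of the same base collapse onto a common shape
  out <- transform_spectra(fp, cal)$absorbance
  expect_gt(min(cor(t(out))), 0.999)
  # new data are corrected against the stored (not re-estimated) reference
  new <- make_set(matrix(5 + 3 * base, 1))
  corrected <- transform_spectra(fp, new)$absorbance[1, ]
  fit <- lm(new$absorbance[1, ] ~ fp$fitted[[1]]$reference)
  expect_equal(corrected,
               (new$absorbance[1, ] - coef(fit)[1]) / coef(fit)[2],
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("in a chain, the MSC reference is the mean of the already-smoothed spectra", {
  set.seed(2)
  cal <- make_set(matrix(rnorm(4 * 20, 1, 0.1), 4, 20))
  fp <- fit_preprocessor(preprocess_spec(step_savgol(5, 2), step_msc()), cal)
  smoothed <- transform_spectra(fit_preprocessor(
    preprocess_spec(step_savgol(5, 2)), cal), cal)$absorbance
  expect_equal(fp$fitted[[2]]$reference, colMeans(smoothed), tolerance = 1e-12)
})

test_that("Savitzky-Golay reproduces polynomials up to its order everywhere", {
  x <- seq(-1, 1, length.out = 41)
  y <- 3 - 2 * x + 0.5 * x^2                   # degree 2
  s <- make_set(matrix(y, 1))
  fp <- fit_preprocessor(preprocess_spec(step_savgol(5, 2)), s)
  out <- transform_spectra(fp, s)$absorbance[1, ]
  expect_equal(out, y, tolerance = 1e-10)      # including truncated edge windows
})

test_that("Savitzky-Golay interior agrees with signal::sgolayfilt", {
  skip_if_not_installed("signal")
  set.seed(3)
  y <- cumsum(rnorm(80))
  s <- make_set(matrix(y, 1))
  fp <- fit_preprocessor(preprocess_spec(step_savgol(11, 3)), s)
  ours <- transform_spectra(fp, s)$absorbance[1, ]
  ref <- signal::sgolayfilt(y, p = 3, n = 11)
  interior <- 6:75
  expect_equal(ours[interior], ref[interior], tolerance = 1e-10)
})

test_that("SNV and mean normalization are idempotent", {
  set.seed(4)
  s <- make_set(matrix(runif(3 * 15, 0.5, 1.5), 3, 15))
  for (step in list(step_snv(), step_meannorm())) {
    fp <- fit_preprocessor(preprocess_spec(step), s)
    once <- transform_spectra(fp, s)
    twice <- transform_spectra(fit_preprocessor(preprocess_spec(step), once), once)
    expect_equal(twice$absorbance, once$absorbance, tolerance = 1e-10)
  }
})

test_that("transforms keep the wavenumber axis and sample order", {
  s <- toy_spectra(n = 5, p = 30)
  fp <- fit_preprocessor(preprocess_spec(step_savgol(7, 2), step_snv()), s)
  out <- transform_spectra(fp, s)
  expect_identical(out$wavenumbers, s$wavenumbers)
  expect_identical(out$sample_ids, s$sample_ids)
  expect_identical(out$ssc, s$ssc)
})

test_that("degenerate spectra fail with the sample named", {
  s <- make_set(rbind(c(1, 2, 3), c(5, 5, 5)))
  fp <- fit_preprocessor(preprocess_spec(step_snv()),
                         make_set(rbind(c(1, 2, 3))))
  expect_error(transform_spectra(fp, s), "S2")
  z <- make_set(rbind(c(1, 2, 3), c(-1, 0, 1)))
  fpm <- fit_preprocessor(preprocess_spec(step_meannorm()),
                          make_set(rbind(c(1, 2, 3))))
  expect_error(transform_spectra(fpm, z), "S2")
})

test_that("spec validation and parsing behave", {
  expect_error(step_savgol(4, 2), "odd")
  expect_error(step_savgol(3, 2), "poly_order")
  sp <- parse_preprocess_spec("savgol:39:2,msc")
  expect_equal(sp$steps[[1]]$window_points, 39L)
  expect_equal(sp$steps[[2]]$method, "msc")
  expect_equal(format(parse_preprocess_spec("raw")), "raw")
  expect_error(parse_preprocess_spec("wavelet"), "unknown")
  s <- make_set(matrix(runif(20), 2, 10))
  expect_error(fit_preprocessor(preprocess_spec(step_savgol(11, 2)), s),
               "exceeds")
})
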
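# shared fixtures, built in code

# small spectra set with a known linear SSC signal in specific columns
toy_spectra <- function(n = 12, p = 20, seed = 42, noise = 0) {
  set.seed(seed)
  wn <- seq(4000, 10000, length.out = p)
  ssc <- runif(n, 11, 17)
  x <- matrix(rnorm(n * p, 0.5, 0.05), n, p)
  x[, 3] <- 0.02 * ssc + rnorm(n, 0, noise)
  x[, 7] <- 0.01 * ssc + rnorm(n, 0, noise)
  spectra_set(x, wn, ssc = ssc, provenance = "toy")
}

# quick full pipeline pieces for the selector tests
msc_calibration <- function(spectra, n_cal = 120) {
  ks <- kennard_stone(spectra, n_cal)
  cal <- subset_samples(spectra, ks$calibration_indices)
  pred <- subset_samples(spectra, ks$prediction_indices)
  fp <- fit_preprocessor(preprocess_spec(step_msc()), cal)
  list(cal = transform_spectra(fp, cal),
       pred = transform_spectra(fp, pred),
       partition = ks)
}

# held-out RMSEP of a PLS model with CV-chosen LV count on given columns
rmsep_on <- function(cal, pred, idx, folds, lv_max = 14) {
  xc <- cal$absorbance[, idx, drop = FALSE]
  cv <- cross_validate(xc, cal$ssc, lv_max, folds)
  m <- fit_pls(xc, cal$ssc, cv$chosen_lv, variable_indices = idx)
  compute_metrics(pred$ssc, predict(m, pred$absorbance[, idx, drop = FALSE]))$rmse
}
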
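#' Calibration performance metrics
#'
#' Computes the standard chemometric evaluation indices for a set of
#' predictions: root mean square error
#' \eqn{RMSE = \sqrt{\sum (\hat y - y)^2 / n}}, bias
#' \eqn{= \mathrm{mean}(\hat y - y)}, and \eqn{R^2}.  By default
#' \eqn{R^2} is the squared Pearson correlation between measured and
#' predicted values; `r2_method = "ssr"` instead returns
#' \eqn{1 - SSE/SST} (which can be negative for poor models and differs
#' from the correlation form whenever predictions are biased or
#' mis-scaled).
#'
#' @param measured measured reference values (degrees Brix).
#' @param predicted model predictions, same length.
#' @param r2_method `"pearson"` (default) or `"ssr"`.
#' @return List with `r2`, `rmse`, `bias`, `n`.
#' @examples
#' compute_metrics(c(1, 2, 3), c(1, 2, 5))
#' @export
compute_metrics <- function(measured, predicted,
                            r2_method = c("pearson", "ssr")) {
  r2_method <- match.arg(r2_method)
  measured <- as.numeric(measured); predicted <- as.numeric(predicted)
  if (length(measured) == 0L || length(measured) != length(predicted))
    stopf("measured and predicted must have equal nonzero length")
  if (any(!is.finite(measured)) || any(!is.finite(predicted)))
    stopf("metrics require finite values")
  resid <- predicted - measured
  rmse <- sqrt(mean(resid^2))
  bias <- mean(resid)
  if (sd(measured) == 0)
    stopf("measured values have zero variance: R^2 is undefined")
  r2 <- if (r2_method == "pearson") {
    if (sd(predicted) == 0) 0 else cor(measured, predicted)^2
  } else {
    1 - sum(resid^2) / sum((measured - mean(measured))^2)
  }
  list(r2 = r2, rmse = rmse, bias = bias, n = length(measured))
}

#' Study configuration
#'
#' Bundles everything [run_study()] needs: the data source, the
#' pretreatment chains to compare, the Kennard-Stone calibration size,
#' the cross-validation settings and the optional wavelength selectors.
#'
#' @param spectra a [spectra_set()] carrying reference SSC, or `NULL` to
#'   simulate from `synthetic`.
#' @param synthetic a [synthetic_config()] used when `spectra` is `NULL`.
#' @param pretreatments named list of [preprocess_spec()] chains to
#'   evaluate (default: raw and the four single pretreatments plus
#'   S-G + MSC, mirroring a standard pretreatment comparison).
#' @param selectors named list of selector configs: entries may be `NULL`
#'   (full spectrum), a [cars_config()] or an [rf_config()].
#' @param n_cal Kennard-Stone calibration set size.
#' @param folds number of cross-validation folds.
#' @param lv_max latent-variable ceiling for full-spectrum models.
#' @param r2_method passed to [compute_metrics()].
#' @param seed master seed for fold assignment.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(spectra = NULL,
                            synthetic = synthetic_config(),
                            pretreatments = default_pretreatments(),
                            selectors = list(none = NULL),
                            n_cal = 120L, folds = 10L, lv_max = 14L,
                            r2_method = "pearson", seed = 1L) {
  if (!is.null(spectra)) {
    stopifnot(inherits(spectra, "spectra_set"))
    if (is.null(spectra$ssc)) stopf("spectra must carry reference SSC values")
  }
  if (is.null(names(pretreatments)) || any(names(pretreatments) == ""))
    names(pretreatments) <- vapply(pretreatments, format, character(1L))
  if (is.null(names(selectors)) || any(names(selectors) == ""))
    stopf("'selectors' must be a named list")
  structure(list(spectra = spectra, synthetic = synthetic,
                 pretreatments = pretreatments, selectors = selectors,
                 n_cal = check_count(n_cal, "n_cal", 4L),
                 folds = check_count(folds, "folds", 2L),
                 lv_max = check_count(lv_max, "lv_max", 1L),
                 r2_method = r2_method,
                 seed = check_count(seed, "seed", 0L)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param savgol_window S-G window (points) used in the smoothing chains.
#' @export
default_pretreatments <- function(savgol_window = 7L) {
  list(raw = preprocess_spec(),
       savgol = preprocess_spec(step_savgol(savgol_window, 2L)),
       msc = preprocess_spec(step_msc()),
       snv = preprocess_spec(step_snv()),
       meannorm = preprocess_spec(step_meannorm()),
       `savgol+msc` = preprocess_spec(step_savgol(savgol_window, 2L), step_msc()))
}

#' Run the full calibration study
#'
#' Executes the end-to-end workflow: simulate-or-load spectra,
#' Kennard-Stone split on the raw spectra, then for every pretreatment
#' chain and every selector: fit the chain on the calibration set only,
#' transform both sets, run the selector on the preprocessed calibration
#' set, choose the latent-variable count by k-fold RMSECV, fit the final
#' PLS model and evaluate it on calibration, cross-validation and
#' prediction sets.  Prediction samples never influence preprocessing
#' fits, selection or training.
#'
#' @param config a [pipeline_config()].
#' @param verbose print one progress line per stage.
#' @return A data.frame (class `study_report`) with one row per
#'   pretreatment x selector combination and columns `pretreatment`,
#'   `selector`, `n_variables`, `n_lv`, `r2_c`, `rmsec`, `r2_cv`,
#'   `rmsecv`, `r2_p`, `rmsep`, `bias`.  The attribute `"details"` holds
#'   the partition, fitted models and selection results.
#' @export
run_study <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  data <- if (is.null(config$spectra)) {
    say("simulate: n=%d p=%d seed=%d", config$synthetic$n_samples,
        config$synthetic$n_wavelengths, config$synthetic$seed)
    generate_spectra(config$synthetic)$spectra
  } else config$spectra
  if (config$n_cal >= n_samples(data))
    stopf("n_cal (%d) must be smaller than the number of samples (%d)",
          config$n_cal, n_samples(data))

  part <- kennard_stone(data, config$n_cal)
  cal <- subset_samples(data, part$calibration_indices)
  pred <- subset_samples(data, part$prediction_indices)
  say("split: %d calibration / %d prediction (Kennard-Stone)",
      n_samples(cal), n_samples(pred))
  folds <- assign_folds(n_samples(cal), config$folds, config$seed)

  rows <- list(); details <- list()
  for (pname in names(config$pretreatments)) {
    fp <- fit_preprocessor(config$pretreatments[[pname]], cal)
    cal_t <- transform_spectra(fp, cal)
    pred_t <- transform_spectra(fp, pred)
    for (sname in names(config$selectors)) {
      scfg <- config$selectors[[sname]]
      sel_res <- NULL
      if (is.null(scfg)) {
        idx <- seq_len(n_wavelengths(cal_t))
      } else if (inherits(scfg, "cars_config")) {
        sel_res <- run_cars(cal_t, config = scfg)
        idx <- sel_res$selected_indices
      } else if (inherits(scfg, "rf_config")) {
        sel_res <- run_random_frog(cal_t, config = scfg)
        idx <- sel_res$selected_indices
      } else stopf("selector '%s' is neither NULL, cars_config nor rf_config",
                   sname)
      say("%s / %s: %d variables", pname, sname, length(idx))
      xc <- cal_t$absorbance[, idx, drop = FALSE]
      xp <- pred_t$absorbance[, idx, drop = FALSE]
      cv <- cross_validate(xc, cal_t$ssc, config$lv_max, folds)
      model <- fit_pls(xc, cal_t$ssc, cv$chosen_lv, variable_indices = idx)
      mc <- compute_metrics(cal_t$ssc, predict(model, xc), config$r2_method)
      mcv <- compute_metrics(cal_t$ssc, cv$cv_predictions[, cv$chosen_lv],
                             config$r2_method)
      mp <- compute_metrics(pred_t$ssc, predict(model, xp), config$r2_method)
      say("%s / %s: lv=%d rmsec=%.4f rmsecv=%.4f rmsep=%.4f",
          pname, sname, cv$chosen_lv, mc$rmse, mcv$rmse, mp$rmse)
      rows[[length(rows) + 1L]] <- data.frame(
        pretreatment = pname, selector = sname,
        n_variables = length(idx), n_lv = cv$chosen_lv,
        r2_c = mc$r2, rmsec = mc$rmse,
        r2_cv = mcv$r2, rmsecv = mcv$rmse,
        r2_p = mp$r2, rmsep = mp$rmse, bias = mp$bias,
        stringsAsFactors = FALSE)
      details[[paste(pname, sname, sep = "/")]] <-
        list(selection = sel_res, indices = idx, cv = cv, model = model)
    }
  }
  report <- do.call(rbind, rows)
  attr(report, "details") <- c(list(partition = part, folds = folds),
                               details)
  class(report) <- c("study_report", class(report))
  report
}

#' Write a study report as delimited text
#'
#' @param report a `study_report` from [run_study()].
#' @param path file path.
#' @export
write_report_csv <- function(report, path) {
  df <- as.data.frame(report)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
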
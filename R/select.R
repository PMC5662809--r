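#' CARS configuration
#'
#' Parameters of competitive adaptive reweighted sampling: the number of
#' Monte-Carlo sampling runs, the fraction of calibration samples drawn
#' per run, and the cross-validation settings used to score each run's
#' variable subset.
#'
#' @param n_runs number of sampling runs N.
#' @param mc_sample_ratio fraction of calibration samples drawn (without
#'   replacement) for the per-run model.
#' @param folds number of cross-validation folds.
#' @param lv_max largest latent-variable count considered.
#' @param seed integer seed; the whole run is reproducible from it.
#' @return A `cars_config`.
#' @export
cars_config <- function(n_runs = 50L, mc_sample_ratio = 0.8, folds = 10L,
                        lv_max = 14L, seed = 1L) {
  ratio <- check_number(mc_sample_ratio, "mc_sample_ratio", 0)
  if (ratio <= 0 || ratio > 1) stopf("'mc_sample_ratio' must be in (0, 1]")
  structure(list(n_runs = check_count(n_runs, "n_runs", 2L),
                 mc_sample_ratio = ratio,
                 folds = check_count(folds, "folds", 2L),
                 lv_max = check_count(lv_max, "lv_max", 1L),
                 seed = check_count(seed, "seed", 0L)),
            class = "cars_config")
}

#' Exponentially decreasing retention schedule
#'
#' The enforced wavelength reduction of CARS keeps a fraction
#' \eqn{r_i = a e^{-k i}} of the p variables at sampling run i.  The two
#' constants are fixed by the boundary conditions \eqn{r_1 = 1} (all
#' variables survive the first run) and \eqn{r_N = 2/p} (only two survive
#' the last), giving \eqn{a = (p/2)^{1/(N-1)}} and
#' \eqn{k = \ln(p/2)/(N-1)}.
#'
#' @param p number of variables.
#' @param n_runs number of sampling runs N.
#' @return Numeric vector of retention ratios, length `n_runs`.
#' @examples
#' edf_schedule(500, 50)[c(1, 50)]   # 1 and 2/500
#' @export
edf_schedule <- function(p, n_runs) {
  p <- check_count(p, "p", 3L)
  n_runs <- check_count(n_runs, "n_runs", 2L)
  a <- (p / 2)^(1 / (n_runs - 1))
  k <- log(p / 2) / (n_runs - 1)
  a * exp(-k * seq_len(n_runs))
}

#' Competitive adaptive reweighted sampling (CARS)
#'
#' Iterative wavelength elimination.  Each sampling run i: (1) draw
#' `ceiling(mc_sample_ratio * M)` calibration samples without replacement
#' and fit a PLS model on the surviving variables (its latent-variable
#' count is the cross-validated choice for the current subset, carried
#' forward from step 5 of the previous run); (2) weight each
#' variable by its normalized absolute regression coefficient; (3) the
#' exponentially decreasing schedule ([edf_schedule()]) enforces keeping
#' only the top `ceiling(p * r_i)` variables by weight; (4) adaptive
#' reweighted sampling then draws that many variables *with* replacement,
#' with probability proportional to weight, and the unique draws survive;
#' (5) the surviving subset is scored by k-fold RMSECV (latent variables
#' chosen by [cross_validate()], capped at `lv_max`) computed on all
#' calibration rows.  The subset with the lowest RMSECV over all runs is
#' returned.  A run whose surviving set has fewer than 2 variables is
#' recorded with RMSECV `Inf` and excluded from the minimum.
#'
#' @param x_cal calibration matrix (samples x variables, p >= 4) or a
#'   [spectra_set()].
#' @param y_cal calibration response; taken from `x_cal$ssc` when omitted
#'   and `x_cal` is a spectra set.
#' @param config a [cars_config()].
#' @return A `cars_result`: `rmsecv_by_run`, `n_vars_by_run`,
#'   `subsets_by_run`, `best_run`, `selected_indices`, `chosen_lv_by_run`.
#' @export
run_cars <- function(x_cal, y_cal = NULL, config = cars_config()) {
  if (inherits(x_cal, "spectra_set")) {
    if (is.null(y_cal)) y_cal <- x_cal$ssc
    x_cal <- x_cal$absorbance
  }
  x_cal <- as.matrix(x_cal); y_cal <- as.numeric(y_cal)
  stopifnot(inherits(config, "cars_config"))
  m <- nrow(x_cal); p <- ncol(x_cal)
  if (p < 4L) stopf("CARS needs at least 4 variables (got %d)", p)
  if (m != length(y_cal)) stopf("x_cal/y_cal size mismatch")
  n_draw <- ceiling(config$mc_sample_ratio * m)
  ratios <- edf_schedule(p, config$n_runs)
  with_seed(config$seed, {
    fold_seed <- sample.int(2^30, 1L)
    folds <- assign_folds(m, config$folds, fold_seed)
    current <- seq_len(p)
    rmsecv <- rep(NA_real_, config$n_runs)
    nvars <- integer(config$n_runs)
    subsets <- vector("list", config$n_runs)
    chosen_lv <- rep(NA_integer_, config$n_runs)
    # LV count of the per-run weight model: cross-validated on the full
    # variable set up front, then carried forward from the most recent
    # subset cross-validation (a ceiling-LV fit overfits and scrambles
    # the coefficient ranking)
    cv0 <- cross_validate(x_cal, y_cal, config$lv_max, folds)
    lv_weight <- cv0$chosen_lv
    for (i in seq_len(config$n_runs)) {
      rows <- sample.int(m, n_draw)
      a_fit <- min(lv_weight, n_draw - 1L, length(current))
      fit <- pls1_path(x_cal[rows, current, drop = FALSE], y_cal[rows], a_fit)
      w <- abs(fit$regression_vector)
      if (sum(w) == 0) w <- rep(1, length(current))
      w <- w / sum(w)
      n_edf <- max(2L, ceiling(p * ratios[i]))      # EDF envelope, in draws
      keep <- current[order(-w, seq_along(w))][seq_len(min(n_edf, length(current)))]
      w_keep <- w[match(keep, current)]
      draws <- sample(keep, n_edf, replace = TRUE, prob = w_keep)
      retained <- sort(unique(draws))
      nvars[i] <- length(retained)
      subsets[[i]] <- retained
      if (length(retained) < 2L) {
        rmsecv[i] <- Inf
        next                                  # keep `current`; can't model 1 var
      }
      cv <- cross_validate(x_cal[, retained, drop = FALSE], y_cal,
                           config$lv_max, folds)
      rmsecv[i] <- cv$rmsecv_by_lv[cv$chosen_lv]
      chosen_lv[i] <- cv$chosen_lv
      lv_weight <- cv$chosen_lv
      current <- retained
    }
    best <- which.min(rmsecv)                 # Inf runs never win
    structure(list(rmsecv_by_run = rmsecv, n_vars_by_run = nvars,
                   subsets_by_run = subsets, best_run = best,
                   selected_indices = subsets[[best]],
                   chosen_lv_by_run = chosen_lv,
                   config = config),
              class = "cars_result")
  })
}

#' @export
print.cars_result <- function(x, ...) {
  cat(sprintf("<cars_result> best run %d of %d: %d variables, RMSECV %.4g\n",
              x$best_run, length(x$rmsecv_by_run),
              length(x$selected_indices), x$rmsecv_by_run[x$best_run]))
  invisible(x)
}

#' Random frog configuration
#'
#' @param n_iterations chain length N.
#' @param q_init number of variables in the initial subset Q.
#' @param theta spread factor of the candidate-size proposal: the proposed
#'   size is drawn from Normal(|V|, theta*|V|) and rounded.
#' @param folds,lv_max cross-validation settings for subset scoring.
#' @param sp_cutoff selection-probability threshold defining the returned
#'   variable set.
#' @param seed integer seed.
#' @return An `rf_config`.
#' @export
rf_config <- function(n_iterations = 1000L, q_init = 2L, theta = 0.3,
                      folds = 10L, lv_max = 14L, sp_cutoff = 0.05,
                      seed = 1L) {
  theta <- check_number(theta, "theta", 0)
  sp_cutoff <- check_number(sp_cutoff, "sp_cutoff")
  if (sp_cutoff <= 0 || sp_cutoff >= 1) stopf("'sp_cutoff' must be in (0, 1)")
  structure(list(n_iterations = check_count(n_iterations, "n_iterations", 1L),
                 q_init = check_count(q_init, "q_init", 1L),
                 theta = theta,
                 folds = check_count(folds, "folds", 2L),
                 lv_max = check_count(lv_max, "lv_max", 1L),
                 sp_cutoff = sp_cutoff,
                 seed = check_count(seed, "seed", 0L)),
            class = "rf_config")
}

#' Random frog wavelength selection
#'
#' A reversible-jump-flavoured chain over variable subsets.  From the
#' current subset V a candidate size Q* is proposed from
#' Normal(|V|, theta|V|), rounded and clipped to [1, p].  The candidate
#' subset is built from V by deleting its lowest-weighted variables or
#' adding the top-weighted outside variables until it has Q* members,
#' where a variable's weight is the absolute value of its collapsed PLS
#' regression coefficient (fitted on V for deletions, on the full
#' variable set for additions).  The candidate is accepted with
#' probability `min(1, perf(V*)/perf(V))` where perf is 1/RMSECV
#' (k-fold, latent variables chosen by [cross_validate()]).  Each
#' variable's selection probability (SP) is the fraction of iterations
#' whose accepted subset contained it; variables with SP at or above
#' `sp_cutoff` form the returned set.
#'
#' @inheritParams run_cars
#' @param config an [rf_config()].
#' @return An `rf_result`: `sp` (length p), `selected_indices`,
#'   `subset_size_trace`, `accepted` (logical trace), `config`.
#' @export
run_random_frog <- function(x_cal, y_cal = NULL, config = rf_config()) {
  if (inherits(x_cal, "spectra_set")) {
    if (is.null(y_cal)) y_cal <- x_cal$ssc
    x_cal <- x_cal$absorbance
  }
  x_cal <- as.matrix(x_cal); y_cal <- as.numeric(y_cal)
  stopifnot(inherits(config, "rf_config"))
  m <- nrow(x_cal); p <- ncol(x_cal)
  if (config$q_init > p) stopf("'q_init' (%d) exceeds p (%d)", config$q_init, p)
  with_seed(config$seed, {
    fold_seed <- sample.int(2^30, 1L)
    folds <- assign_folds(m, config$folds, fold_seed)
    score <- function(v) {                    # (1 / RMSECV, chosen lv); NA on failure
      if (length(v) < 1L) return(list(perf = NA_real_, lv = NA_integer_))
      cv <- tryCatch(cross_validate(x_cal[, v, drop = FALSE], y_cal,
                                    config$lv_max, folds),
                     error = function(e) NULL)
      if (is.null(cv)) return(list(perf = NA_real_, lv = NA_integer_))
      r <- cv$rmsecv_by_lv[cv$chosen_lv]
      if (!is.finite(r) || r <= 0) return(list(perf = NA_real_, lv = NA_integer_))
      list(perf = 1 / r, lv = cv$chosen_lv)
    }
    # weight models use cross-validated LV counts: ceiling-LV fits overfit
    # and scramble the coefficient ranking
    cv_full <- cross_validate(x_cal, y_cal, config$lv_max, folds)
    lv_full <- cv_full$chosen_lv
    coef_weights <- function(v, lv) {         # |regression coefficients| on set v
      fit <- pls1_path(x_cal[, v, drop = FALSE], y_cal,
                       min(lv, m - 1L, length(v)))
      abs(fit$regression_vector)
    }
    v_cur <- sort(sample.int(p, config$q_init))
    sc <- score(v_cur)
    perf_cur <- sc$perf; lv_cur <- if (is.na(sc$lv)) 1L else sc$lv
    if (is.na(perf_cur)) stopf("initial subset could not be cross-validated")
    counts <- integer(p)
    size_trace <- integer(config$n_iterations)
    accepted <- logical(config$n_iterations)
    for (it in seq_len(config$n_iterations)) {
      q_star <- as.integer(round(rnorm(1L, length(v_cur),
                                       config$theta * length(v_cur))))
      q_star <- max(1L, min(p, q_star))
      if (q_star == length(v_cur)) {
        v_star <- v_cur
      } else if (q_star < length(v_cur)) {
        w <- coef_weights(v_cur, lv_cur)
        v_star <- sort(v_cur[order(-w, seq_along(w))][seq_len(q_star)])
      } else {
        w_full <- coef_weights(seq_len(p), lv_full)
        outside <- setdiff(seq_len(p), v_cur)
        w_out <- w_full[outside]
        add <- outside[order(-w_out, seq_along(w_out))][seq_len(q_star - length(v_cur))]
        v_star <- sort(c(v_cur, add))
      }
      if (identical(v_star, v_cur)) {
        accepted[it] <- TRUE
      } else {
        sc <- score(v_star)
        if (!is.na(sc$perf) &&
            runif(1L) < min(1, sc$perf / perf_cur)) {
          v_cur <- v_star
          perf_cur <- sc$perf
          lv_cur <- sc$lv
          accepted[it] <- TRUE
        }
      }
      counts[v_cur] <- counts[v_cur] + 1L
      size_trace[it] <- length(v_cur)
    }
    sp <- counts / config$n_iterations
    structure(list(sp = sp,
                   selected_indices = which(sp >= config$sp_cutoff),
                   subset_size_trace = size_trace,
                   accepted = accepted,
                   config = config),
              class = "rf_result")
  })
}

#' @export
print.rf_result <- function(x, ...) {
  cat(sprintf("<rf_result> %d variables with SP >= %.2g after %d iterations\n",
              length(x$selected_indices), x$config$sp_cutoff,
              x$config$n_iterations))
  invisible(x)
}

#' Restrict a spectra set to selected wavelengths
#'
#' @param data a [spectra_set()].
#' @param indices column positions to keep, in the order given.
#' @return A [spectra_set()] with the selected columns.
#' @export
apply_selection <- function(data, indices) {
  stopifnot(inherits(data, "spectra_set"))
  indices <- as.integer(indices)
  if (length(indices) == 0L)
    stopf("empty wavelength selection: a model needs at least one variable")
  if (any(indices < 1L | indices > n_wavelengths(data)))
    stopf("selection index out of range 1..%d", n_wavelengths(data))
  if (length(indices) > 1L && any(diff(indices) <= 0))
    stopf("selection indices must be strictly increasing (the wavenumber axis stays monotone)")
  spectra_set(data$absorbance[, indices, drop = FALSE],
              data$wavenumbers[indices], data$sample_ids, data$ssc,
              provenance = paste0(data$provenance, "|subset"))
}
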
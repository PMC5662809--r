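#' Partial least squares regression (NIPALS, single response)
#'
#' Fits a mean-centred PLS1 model by NIPALS-style sequential extraction.
#' Per component: the weight vector is the covariance of the residual X
#' with the residual y (normalized), scores \eqn{t = X_{res} w}, X-loading
#' \eqn{p = X_{res}' t / t't}, y-loading \eqn{q = y_{res}' t / t't},
#' y-score \eqn{u} = current y residual, inner coefficient
#' \eqn{b = u't / t't}, then X and y residuals are deflated.  The
#' per-component quantities are collapsed into a single regression vector
#' \eqn{\beta = W (P'W)^{-1} q} such that prediction is
#' \eqn{(x - \bar x) \beta + \bar y}; the score-space path and the
#' collapsed path give identical predictions.
#'
#' Variables are centred but not scaled: absorbance variables share units.
#' If the residual covariance collapses before `n_lv` components (exactly
#' collinear data), the remaining components are zero and predictions stop
#' changing.
#'
#' @param x numeric matrix (samples x variables).
#' @param y numeric response vector (degrees Brix).
#' @param n_lv number of latent variables, at most `min(nrow(x)-1, ncol(x))`.
#' @param variable_indices optional integer tag recording which columns of
#'   a parent spectra matrix `x` is (bookkeeping for wavelength-selected
#'   models).
#' @return A `pls_model` with fields `n_lv`, `x_mean`, `y_mean`, `weights`
#'   (W), `x_scores` (T), `x_loadings` (P), `y_scores` (U), `y_loadings`
#'   (q, vector), `inner_coefficients` (b, vector), `regression_vector`,
#'   `coefficient_path` (variables x n_lv matrix, column a = collapsed
#'   coefficients of the a-component model) and `variable_indices`.
#' @examples
#' x <- matrix(rnorm(60), 20, 3); y <- x %*% c(1, -1, 2) + rnorm(20, 0, .1)
#' m <- fit_pls(x, y, 3)
#' head(predict(m, x))
#' @export
fit_pls <- function(x, y, n_lv, variable_indices = seq_len(ncol(x))) {
  x <- as.matrix(x); storage.mode(x) <- "double"
  y <- as.numeric(y)
  if (nrow(x) != length(y))
    stopf("x has %d rows but y has %d values", nrow(x), length(y))
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stopf("x and y must be finite")
  if (sd(y) == 0) stopf("y has zero variance")
  n_lv <- check_count(n_lv, "n_lv", 1L)
  cap <- min(nrow(x) - 1L, ncol(x))
  if (n_lv > cap)
    stopf("'n_lv' (%d) exceeds min(samples-1, variables) = %d", n_lv, cap)
  fit <- pls1_path(x, y, n_lv)
  structure(c(fit, list(variable_indices = as.integer(variable_indices))),
            class = "pls_model")
}

# workhorse: full component path in one pass (used by fit_pls and CV)
pls1_path <- function(x, y, a_max) {
  n <- nrow(x); p <- ncol(x)
  x_mean <- colMeans(x); y_mean <- mean(y)
  xr <- sweep(x, 2L, x_mean)
  yr <- y - y_mean
  W <- P <- matrix(0, p, a_max)
  Tm <- U <- matrix(0, n, a_max)
  q <- b <- numeric(a_max)
  scale0 <- max(1, sqrt(sum(xr^2)) * sqrt(sum(yr^2)))
  for (a in seq_len(a_max)) {
    w <- crossprod(xr, yr)                    # covariance direction
    nw <- sqrt(sum(w^2))
    if (nw <= 1e-12 * scale0) break           # residual collapsed
    w <- w / nw
    t_ <- as.numeric(xr %*% w)
    tt <- sum(t_^2)
    if (tt <= (1e-12 * scale0)^2) break
    p_ <- as.numeric(crossprod(xr, t_)) / tt
    q_ <- sum(yr * t_) / tt
    W[, a] <- w; P[, a] <- p_; Tm[, a] <- t_
    U[, a] <- yr                              # y-score (single response)
    b[a] <- sum(yr * t_) / tt                 # inner relation U = bT
    q[a] <- q_
    xr <- xr - tcrossprod(t_, p_)
    yr <- yr - t_ * q_
  }
  # collapsed coefficients for every model size 1..a_max
  R <- crossprod(P, W)
  coefs <- matrix(0, p, a_max)
  prev <- rep(0, p)
  for (a in seq_len(a_max)) {
    if (all(W[, a] == 0)) { coefs[, a] <- prev; next }
    coefs[, a] <- W[, 1:a, drop = FALSE] %*%
      solve(R[1:a, 1:a, drop = FALSE], q[1:a])
    prev <- coefs[, a]
  }
  list(n_lv = a_max, x_mean = x_mean, y_mean = y_mean,
       weights = W, x_scores = Tm, x_loadings = P, y_scores = U,
       y_loadings = q, inner_coefficients = b,
       regression_vector = coefs[, a_max],
       coefficient_path = coefs)
}

#' Predict from a PLS model
#'
#' @param object a `pls_model`.
#' @param x matrix of new samples with as many columns as the model's
#'   `variable_indices`.
#' @param n_lv optionally predict with a smaller number of components than
#'   the model was fitted with.
#' @param ... unused.
#' @return Numeric vector of predictions (degrees Brix).
#' @export
predict.pls_model <- function(object, x, n_lv = object$n_lv, ...) {
  x <- as.matrix(x)
  if (ncol(x) != length(object$variable_indices))
    stopf("x has %d columns, model expects %d", ncol(x),
          length(object$variable_indices))
  n_lv <- check_count(n_lv, "n_lv", 1L)
  if (n_lv > object$n_lv)
    stopf("'n_lv' (%d) exceeds the fitted components (%d)", n_lv, object$n_lv)
  beta <- object$coefficient_path[, n_lv]
  as.numeric(sweep(x, 2L, object$x_mean) %*% beta) + object$y_mean
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> %d latent variables on %d variables\n",
              x$n_lv, length(x$variable_indices)))
  invisible(x)
}

#' Cross-validated latent-variable selection
#'
#' k-fold cross-validation of PLS over component counts 1..`lv_max`.  For
#' each fold the model (including the centring step) is refitted on the
#' complement and the held-out samples are predicted at every component
#' count; `rmsecv_by_lv[a]` is the root mean square of the pooled held-out
#' residuals of the a-component model.  The chosen size is the smallest
#' component count whose RMSECV is within 1e-12 of the minimum
#' (parsimonious tie-break).
#'
#' @param x matrix (samples x variables).
#' @param y response vector.
#' @param lv_max largest component count to evaluate; silently capped at
#'   what the smallest training fold supports.
#' @param folds a [assign_folds()] result covering the samples of `x`.
#' @return A `cv_result`: `rmsecv_by_lv`, `chosen_lv`, `lv_max`,
#'   `cv_predictions` (samples x lv_max matrix of held-out predictions).
#' @export
cross_validate <- function(x, y, lv_max, folds) {
  x <- as.matrix(x); y <- as.numeric(y)
  stopifnot(inherits(folds, "fold_assignment"))
  n <- nrow(x)
  if (length(folds$fold_of_sample) != n)
    stopf("fold assignment covers %d samples, x has %d",
          length(folds$fold_of_sample), n)
  lv_max <- check_count(lv_max, "lv_max", 1L)
  sizes <- tabulate(folds$fold_of_sample, folds$k)
  if (n - max(sizes) < 2L)
    stopf("a fold leaves fewer than 2 training samples")
  a_eff <- min(lv_max, n - max(sizes) - 1L, ncol(x))
  pred <- matrix(NA_real_, n, a_eff)
  for (f in seq_len(folds$k)) {
    hold <- which(folds$fold_of_sample == f)
    if (length(hold) == 0L) next
    fit <- pls1_path(x[-hold, , drop = FALSE], y[-hold], a_eff)
    xc <- sweep(x[hold, , drop = FALSE], 2L, fit$x_mean)
    pred[hold, ] <- xc %*% fit$coefficient_path + fit$y_mean
  }
  resid <- pred - y
  rmsecv <- sqrt(colMeans(resid^2))
  chosen <- which(rmsecv <= min(rmsecv) + 1e-12)[1L]
  structure(list(rmsecv_by_lv = rmsecv, chosen_lv = as.integer(chosen),
                 lv_max = a_eff, cv_predictions = pred),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> chosen %d of %d LVs, RMSECV %.4g\n",
              x$chosen_lv, x$lv_max, x$rmsecv_by_lv[x$chosen_lv]))
  invisible(x)
}
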
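#' Pretreatment chain specification
#'
#' A `preprocess_spec` is an ordered list of pretreatment steps applied to
#' spectra row by row.  Available steps:
#' \describe{
#'   \item{savgol}{Savitzky-Golay smoothing: local least-squares polynomial
#'     of order `poly_order` over a moving window of `window_points`
#'     points (odd).  At the edges the polynomial is fitted on the
#'     truncated asymmetric window, so the spectrum keeps its length
#'     without padding.}
#'   \item{msc}{Multiplicative scatter correction: each spectrum s is
#'     regressed on a reference spectrum r, s ~ a + b r, and corrected to
#'     (s - a)/b.  The reference is the column-wise mean of the
#'     calibration spectra at that point of the chain (never prediction
#'     samples), or an explicit vector.}
#'   \item{snv}{Standard normal variate: each spectrum is centred and
#'     scaled to unit standard deviation (n-1 denominator).}
#'   \item{meannorm}{Mean normalization: each spectrum is divided by its
#'     own mean.}
#' }
#'
#' @param ... steps built with [step_savgol()], [step_msc()], [step_snv()],
#'   [step_meannorm()], in application order.  No steps gives the identity
#'   pipeline.
#' @return A `preprocess_spec`.
#' @examples
#' sp <- preprocess_spec(step_savgol(39, 2), step_msc())
#' format(sp)
#' @export
preprocess_spec <- function(...) {
  steps <- list(...)
  if (length(steps) == 1L && is.list(steps[[1L]]) &&
      is.null(steps[[1L]]$method))
    steps <- steps[[1L]]
  for (s in steps) {
    if (!is.list(s) || is.null(s$method) ||
        !s$method %in% c("savgol", "msc", "snv", "meannorm"))
      stopf("each step must be built with step_savgol/step_msc/step_snv/step_meannorm")
  }
  structure(list(steps = steps), class = "preprocess_spec")
}

#' @rdname preprocess_spec
#' @param window_points odd window length, >= poly_order + 2.
#' @param poly_order polynomial order for the local fit.
#' @export
step_savgol <- function(window_points = 39L, poly_order = 2L) {
  window_points <- check_count(window_points, "window_points", 3L)
  poly_order <- check_count(poly_order, "poly_order", 0L)
  if (window_points %% 2L == 0L)
    stopf("'window_points' must be odd (got %d)", window_points)
  if (window_points < poly_order + 2L)
    stopf("'window_points' (%d) must be >= poly_order + 2 (%d)",
          window_points, poly_order + 2L)
  list(method = "savgol", window_points = window_points,
       poly_order = poly_order)
}

#' @rdname preprocess_spec
#' @param reference `"calibration-mean"` (default) or an explicit numeric
#'   reference spectrum.
#' @export
step_msc <- function(reference = "calibration-mean") {
  if (!(identical(reference, "calibration-mean") || is.numeric(reference)))
    stopf("msc reference must be \"calibration-mean\" or a numeric vector")
  list(method = "msc", reference = reference)
}

#' @rdname preprocess_spec
#' @export
step_snv <- function() list(method = "snv")

#' @rdname preprocess_spec
#' @export
step_meannorm <- function() list(method = "meannorm")

#' @export
format.preprocess_spec <- function(x, ...) {
  if (length(x$steps) == 0L) return("raw")
  paste(vapply(x$steps, function(s) switch(s$method,
    savgol = sprintf("savgol(%d,%d)", s$window_points, s$poly_order),
    msc = "msc", snv = "snv", meannorm = "meannorm"), character(1L)),
    collapse = "+")
}

#' @export
print.preprocess_spec <- function(x, ...) {
  cat("<preprocess_spec>", format(x), "\n"); invisible(x)
}

#' Parse a pretreatment chain from text
#'
#' Accepts comma-separated step names, e.g. `"savgol:39:2,msc"`;
#' `savgol` takes optional `:window:order` suffixes.
#'
#' @param text the chain description; `""` or `"raw"` is the identity.
#' @return A [preprocess_spec()].
#' @export
parse_preprocess_spec <- function(text) {
  text <- trimws(text)
  if (text == "" || text == "raw") return(preprocess_spec())
  parts <- strsplit(text, ",", fixed = TRUE)[[1L]]
  steps <- lapply(parts, function(p) {
    f <- strsplit(trimws(p), ":", fixed = TRUE)[[1L]]
    switch(f[1L],
      savgol = step_savgol(if (length(f) > 1L) as.integer(f[2L]) else 39L,
                           if (length(f) > 2L) as.integer(f[3L]) else 2L),
      msc = step_msc(),
      snv = step_snv(),
      meannorm = step_meannorm(),
      stopf("unknown pretreatment step '%s'", f[1L]))
  })
  do.call(preprocess_spec, steps)
}

#' Fit a pretreatment chain on a calibration set
#'
#' Walks the chain over the calibration spectra in order.  The only step
#' with fitted state is MSC with a `"calibration-mean"` reference: its
#' stored reference is the column-wise mean of the calibration spectra
#' *after all preceding steps*.  The same stored reference is reused when
#' transforming new (prediction) samples — prediction data never
#' influence the fit.
#'
#' @param spec a [preprocess_spec()].
#' @param calibration a [spectra_set()]; must be non-empty.
#' @return A `fitted_preprocessor`.
#' @export
fit_preprocessor <- function(spec, calibration) {
  stopifnot(inherits(spec, "preprocess_spec"),
            inherits(calibration, "spectra_set"))
  if (n_samples(calibration) < 1L) stopf("calibration set is empty")
  x <- calibration$absorbance
  ids <- calibration$sample_ids
  fitted <- vector("list", length(spec$steps))
  for (k in seq_along(spec$steps)) {
    s <- spec$steps[[k]]
    if (s$method == "msc" && identical(s$reference, "calibration-mean")) {
      ref <- colMeans(x)
      fitted[[k]] <- list(reference = ref)
      x <- apply_step(s, x, ids, ref)
    } else {
      ref <- if (s$method == "msc") as.numeric(s$reference) else NULL
      fitted[[k]] <- if (is.null(ref)) list() else list(reference = ref)
      x <- apply_step(s, x, ids, ref)
    }
  }
  structure(list(spec = spec, fitted = fitted,
                 wavenumbers = calibration$wavenumbers),
            class = "fitted_preprocessor")
}

#' Apply a fitted pretreatment chain
#'
#' @param fp a `fitted_preprocessor` from [fit_preprocessor()].
#' @param data a [spectra_set()] on the same wavenumber axis as the
#'   fitting data.
#' @return A [spectra_set()] with transformed absorbance; wavenumber axis,
#'   sample order and SSC are untouched.
#' @export
transform_spectra <- function(fp, data) {
  stopifnot(inherits(fp, "fitted_preprocessor"), inherits(data, "spectra_set"))
  if (!isTRUE(all.equal(fp$wavenumbers, data$wavenumbers)))
    stopf("data wavenumber axis differs from the axis the chain was fitted on")
  x <- data$absorbance
  for (k in seq_along(fp$spec$steps)) {
    s <- fp$spec$steps[[k]]
    x <- apply_step(s, x, data$sample_ids, fp$fitted[[k]]$reference)
  }
  label <- format(fp$spec)
  spectra_set(x, data$wavenumbers, data$sample_ids, data$ssc,
              provenance = if (label == "raw") data$provenance
                           else paste0(data$provenance, "|", label))
}

apply_step <- function(s, x, ids, reference = NULL) {
  switch(s$method,
    snv = {
      mu <- rowMeans(x)
      sdev <- apply(x, 1L, sd)
      bad <- which(sdev == 0)
      if (length(bad))
        stopf("snv: zero spectral standard deviation for sample '%s'", ids[bad[1L]])
      (x - mu) / sdev
    },
    meannorm = {
      mu <- rowMeans(x)
      bad <- which(mu == 0)
      if (length(bad))
        stopf("meannorm: zero spectral mean for sample '%s'", ids[bad[1L]])
      x / mu
    },
    msc = {
      if (is.null(reference)) stopf("msc step has no fitted reference")
      rc <- reference - mean(reference)
      denom <- sum(rc^2)
      if (denom == 0) stopf("msc: constant reference spectrum")
      b <- as.numeric((x - rowMeans(x)) %*% rc) / denom
      bad <- which(b == 0)
      if (length(bad))
        stopf("msc: zero multiplicative coefficient for sample '%s'", ids[bad[1L]])
      a <- rowMeans(x) - b * mean(reference)
      (x - a) / b
    },
    savgol = savgol_smooth(x, s$window_points, s$poly_order))
}

# Savitzky-Golay smoothing of the rows of x.  Interior points use the
# symmetric window; each edge point uses the window truncated at the
# spectrum boundary (asymmetric local fit, no padding).
savgol_smooth <- function(x, window_points, poly_order) {
  p <- ncol(x)
  if (window_points > p)
    stopf("savgol window (%d points) exceeds spectrum length (%d)",
          window_points, p)
  h <- (window_points - 1L) %/% 2L
  # value-at-target row of the local least-squares projection for offsets z
  proj_row <- function(z) {
    A <- outer(z, 0:poly_order, "^")
    as.numeric(solve(crossprod(A), t(A))[1L, ])
  }
  out <- matrix(0, nrow(x), p)
  # interior: single symmetric coefficient vector applied by shifted sums
  w_int <- proj_row(seq(-h, h))
  interior <- (h + 1L):(p - h)
  for (k in seq(-h, h))
    out[, interior] <- out[, interior] + w_int[k + h + 1L] * x[, interior + k]
  # edges: truncated windows
  for (i in seq_len(h)) {
    # left edge: window 1..(i+h), target offset 0 at position i
    out[, i] <- x[, 1L:(i + h), drop = FALSE] %*% proj_row(seq(1L - i, h))
    # right edge mirror: window (j-h)..p for j = p-i+1
    j <- p - i + 1L
    out[, j] <- x[, (j - h):p, drop = FALSE] %*% proj_row(seq(-h, i - 1L))
  }
  out
}
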
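#' Kennard-Stone sample set partitioning
#'
#' Selects a representative calibration subset by the maximin-distance
#' rule: the first two selections are the globally farthest sample pair
#' under the Euclidean distance
#' \eqn{d(p,q) = \sqrt{\sum_j (x_p(j) - x_q(j))^2}}; each subsequent
#' selection is the unselected sample whose minimum distance to the
#' already-selected set is largest.  Remaining samples form the prediction
#' set.  Ties are broken by the lowest sample index, so the procedure is
#' fully deterministic.
#'
#' @param x numeric matrix of sample vectors (rows), or a [spectra_set()]
#'   whose absorbance matrix is used.
#' @param n_select number of calibration samples, between 2 and `nrow(x)`.
#' @return A `partition_result`: list with `calibration_indices` (in
#'   selection order), `prediction_indices`, and `n_total`.
#' @examples
#' kennard_stone(matrix(c(0, 1, 2, 10)), 3)
#' @export
kennard_stone <- function(x, n_select) {
  if (inherits(x, "spectra_set")) x <- x$absorbance
  x <- as.matrix(x)
  m <- nrow(x)
  if (any(!is.finite(x))) stopf("x contains non-finite values")
  n_select <- check_count(n_select, "n_select", 2L)
  if (n_select > m)
    stopf("'n_select' (%d) exceeds the number of samples (%d)", n_select, m)
  d <- as.matrix(dist(x))
  # farthest pair; ties -> smallest (i, j) in row-major order
  mx <- max(d)
  hits <- which(d == mx, arr.ind = TRUE)
  hits <- hits[hits[, 1L] < hits[, 2L], , drop = FALSE]
  hits <- hits[order(hits[, 1L], hits[, 2L]), , drop = FALSE]
  sel <- as.integer(hits[1L, ])
  remaining <- setdiff(seq_len(m), sel)
  mind <- pmin(d[, sel[1L]], d[, sel[2L]])
  while (length(sel) < n_select) {
    cand <- remaining[mind[remaining] == max(mind[remaining])]
    pick <- min(cand)                         # tie-break: lowest index
    sel <- c(sel, pick)
    remaining <- setdiff(remaining, pick)
    mind <- pmin(mind, d[, pick])
  }
  structure(list(calibration_indices = sel,
                 prediction_indices = remaining,
                 n_total = m),
            class = "partition_result")
}

#' @export
print.partition_result <- function(x, ...) {
  cat(sprintf("<partition_result> %d calibration / %d prediction of %d samples\n",
              length(x$calibration_indices), length(x$prediction_indices),
              x$n_total))
  invisible(x)
}

#' Deterministic k-fold assignment
#'
#' A seeded random permutation of the samples is dealt round-robin into
#' `k` folds, so fold sizes differ by at most one and the same
#' `(n_samples, k, seed)` always gives the same folds.
#'
#' @param n_samples number of samples.
#' @param k number of folds, between 2 and `n_samples`.
#' @param seed integer seed.
#' @return A `fold_assignment`: list with `k`, `fold_of_sample` (integer
#'   fold label per sample) and `seed`.
#' @export
assign_folds <- function(n_samples, k, seed) {
  n_samples <- check_count(n_samples, "n_samples", 2L)
  k <- check_count(k, "k", 2L)
  seed <- check_count(seed, "seed", 0L)
  if (k > n_samples)
    stopf("'k' (%d) exceeds the number of samples (%d)", k, n_samples)
  perm <- with_seed(seed, sample.int(n_samples))
  fold <- integer(n_samples)
  fold[perm] <- rep_len(seq_len(k), n_samples)
  structure(list(k = k, fold_of_sample = fold, seed = seed),
            class = "fold_assignment")
}
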
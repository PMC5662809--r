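#' Spectra container
#'
#' A `spectra_set` bundles an absorbance matrix (samples x wavelengths,
#' log(1/R) units) with its wavenumber axis (cm^-1, strictly increasing),
#' sample identifiers, and optionally a per-sample reference SSC vector
#' (degrees Brix).  It is the X (and y) of every stage of the workflow.
#'
#' @param absorbance numeric matrix, one row per sample, one column per
#'   wavelength point; all values must be finite.
#' @param wavenumbers numeric vector of wavenumbers in cm^-1, strictly
#'   increasing, one per column of `absorbance`.
#' @param sample_ids character vector of unique sample identifiers; defaults
#'   to `"S1" ... "Sn"`.
#' @param ssc optional numeric vector of reference SSC values (degrees
#'   Brix), one per sample.
#' @param provenance free-text tag describing how the data were obtained
#'   (e.g. `"raw"`, `"synthetic"`, or a pretreatment chain label).
#' @return An object of class `spectra_set`.
#' @examples
#' s <- spectra_set(matrix(rnorm(6), 2, 3), c(4000, 5000, 6000))
#' n_samples(s)
#' @export
spectra_set <- function(absorbance, wavenumbers, sample_ids = NULL,
                        ssc = NULL, provenance = "raw") {
  absorbance <- as.matrix(absorbance)
  storage.mode(absorbance) <- "double"
  wavenumbers <- as.numeric(wavenumbers)
  if (ncol(absorbance) != length(wavenumbers))
    stopf("absorbance has %d columns but %d wavenumbers were given",
          ncol(absorbance), length(wavenumbers))
  if (any(!is.finite(absorbance)))
    stopf("absorbance contains non-finite values")
  if (length(wavenumbers) > 1L && any(diff(wavenumbers) <= 0))
    stopf("wavenumbers must be strictly increasing")
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(absorbance)))
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != nrow(absorbance))
    stopf("%d sample_ids for %d spectra", length(sample_ids), nrow(absorbance))
  if (anyDuplicated(sample_ids))
    stopf("duplicate sample ID: %s", sample_ids[duplicated(sample_ids)][1L])
  if (!is.null(ssc)) {
    ssc <- as.numeric(ssc)
    if (length(ssc) != nrow(absorbance))
      stopf("ssc has %d values for %d samples", length(ssc), nrow(absorbance))
    if (any(!is.finite(ssc))) stopf("ssc contains non-finite values")
  }
  dimnames(absorbance) <- NULL
  structure(list(sample_ids = sample_ids, wavenumbers = wavenumbers,
                 absorbance = absorbance, ssc = ssc,
                 provenance = as.character(provenance)[1L]),
            class = "spectra_set")
}

#' @rdname spectra_set
#' @param x a `spectra_set`.
#' @export
n_samples <- function(x) nrow(x$absorbance)

#' @rdname spectra_set
#' @export
n_wavelengths <- function(x) ncol(x$absorbance)

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("<spectra_set> %d samples x %d wavelengths (%.0f-%.0f cm^-1)\n",
              n_samples(x), n_wavelengths(x),
              min(x$wavenumbers), max(x$wavenumbers)))
  cat(sprintf("  provenance: %s; reference SSC: %s\n", x$provenance,
              if (is.null(x$ssc)) "absent" else
                sprintf("%.2f-%.2f Brix", min(x$ssc), max(x$ssc))))
  invisible(x)
}

#' Subset samples of a spectra set
#'
#' @param x a `spectra_set`.
#' @param i integer vector of sample (row) positions.
#' @return A `spectra_set` with the selected samples, order preserved.
#' @export
subset_samples <- function(x, i) {
  i <- as.integer(i)
  if (length(i) == 0L || any(i < 1L | i > n_samples(x)))
    stopf("sample indices out of range 1..%d", n_samples(x))
  spectra_set(x$absorbance[i, , drop = FALSE], x$wavenumbers,
              x$sample_ids[i], if (!is.null(x$ssc)) x$ssc[i], x$provenance)
}

#' Write / read spectra as delimited text
#'
#' The file format is comma-separated text: the header row holds the literal
#' `sample_id` followed by the wavenumbers in ascending order; each
#' subsequent row holds a sample ID followed by that sample's absorbance
#' values.  Values are written with 15 significant digits so that a
#' write/read round trip reproduces the matrix to full stored precision.
#'
#' @param x a `spectra_set`.
#' @param path file path to write to / read from.
#' @return `read_spectra_csv()` returns a `spectra_set` (without SSC; see
#'   [read_reference_csv()]); `write_spectra_csv()` returns `path`
#'   invisibly.
#' @export
write_spectra_csv <- function(x, path) {
  stopifnot(inherits(x, "spectra_set"))
  header <- paste(c("sample_id", sprintf("%.15g", x$wavenumbers)),
                  collapse = ",")
  rows <- vapply(seq_len(n_samples(x)), function(i)
    paste(c(x$sample_ids[i], sprintf("%.15g", x$absorbance[i, ])),
          collapse = ","), character(1L))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' @rdname write_spectra_csv
#' @export
read_spectra_csv <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L) stopf("'%s': need a header row and at least one sample", path)
  fields <- strsplit(lines, ",", fixed = TRUE)
  header <- fields[[1L]]
  if (header[1L] != "sample_id")
    stopf("'%s': header must start with 'sample_id'", path)
  wn <- suppressWarnings(as.numeric(header[-1L]))
  if (any(is.na(wn)))
    stopf("'%s': non-numeric wavenumber in header (column %d)",
          path, which(is.na(wn))[1L] + 1L)
  p <- length(wn)
  ids <- character(length(lines) - 1L)
  mat <- matrix(NA_real_, length(lines) - 1L, p)
  for (r in 2L:length(lines)) {
    f <- fields[[r]]
    if (length(f) != p + 1L)
      stopf("'%s': row %d has %d fields, expected %d", path, r, length(f), p + 1L)
    vals <- suppressWarnings(as.numeric(f[-1L]))
    if (any(is.na(vals)))
      stopf("'%s': non-numeric absorbance in row %d", path, r)
    ids[r - 1L] <- f[1L]
    mat[r - 1L, ] <- vals
  }
  if (anyDuplicated(ids))
    stopf("'%s': duplicate sample ID '%s' (row %d)", path,
          ids[duplicated(ids)][1L], which(duplicated(ids))[1L] + 1L)
  spectra_set(mat, wn, ids, provenance = sprintf("read:%s", basename(path)))
}

#' Write / read a reference SSC table
#'
#' Two-column comma-separated text: `sample_id,ssc`.
#'
#' @param x a `spectra_set` carrying reference SSC values.
#' @param path file path.
#' @return `read_reference_csv()` returns a data.frame with columns
#'   `sample_id` and `ssc`.
#' @export
write_reference_csv <- function(x, path) {
  stopifnot(inherits(x, "spectra_set"))
  if (is.null(x$ssc)) stopf("spectra set carries no reference SSC values")
  writeLines(c("sample_id,ssc",
               sprintf("%s,%.15g", x$sample_ids, x$ssc)), path)
  invisible(path)
}

#' @rdname write_reference_csv
#' @export
read_reference_csv <- function(path) {
  df <- read.csv(path, colClasses = c("character", "numeric"))
  if (!identical(names(df), c("sample_id", "ssc")))
    stopf("'%s': expected header 'sample_id,ssc'", path)
  df
}
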
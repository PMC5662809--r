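#' Configuration for the synthetic FT-NIR spectra generator
#'
#' Describes a simulated diffuse-reflectance NIR experiment: the wavenumber
#' grid, analyte (sugar-linked) and interferent absorption bands, the
#' distribution of the reference SSC values, and the magnitudes of the
#' corruption terms (per-sample multiplicative/additive scatter, smooth
#' baseline curvature, white noise).
#'
#' Bands are Gaussian in wavenumber: a band `(center, width, intensity)`
#' contributes `intensity * exp(-(v - center)^2 / (2 width^2))` absorbance
#' units per unit concentration.  Analyte band amplitudes scale linearly
#' with each sample's SSC.  Interferent band amplitudes are drawn per
#' sample from `Uniform(1 - variation, 1 + variation) * intensity`,
#' emulating constituents (mostly water) whose concentration varies a
#' little between fruit, independently of sugar content; the interferent
#' background dominates the spectrum, as water does in fruit NIR, while
#' the per-sample scatter terms dominate the between-sample variance.
#'
#' The default SSC distribution (mean 13.42, sd 1.28 degrees Brix,
#' truncated to [10.81, 17.13]) matches the descriptive statistics of a
#' typical 160-apple FT-NIR study; truncation is by rejection sampling so
#' the bounds are exact.
#'
#' @param n_samples number of samples (>= 4).
#' @param n_wavelengths number of wavelength points (>= 8); the grid is
#'   uniform over `wavenumber_range`.
#' @param wavenumber_range length-2 numeric, low and high wavenumber in
#'   cm^-1.
#' @param analyte_bands data.frame with columns `center` (cm^-1), `width`
#'   (cm^-1), `intensity` (absorbance per degree Brix); must be non-empty
#'   with all centers inside `wavenumber_range`.
#' @param interferent_bands same structure plus a `variation` column:
#'   `intensity` is the mean absorbance amplitude of the band and
#'   `variation` the half-width of its per-sample uniform relative
#'   amplitude jitter.  May have zero rows.
#' @param ssc_mean,ssc_sd mean and sd of the SSC distribution (Brix).
#' @param ssc_bounds length-2 numeric truncation bounds (Brix),
#'   bracketing `ssc_mean`.
#' @param scatter_slope_sd sd of the per-sample multiplicative scatter
#'   deviation b (emitted spectrum is scaled by 1 + b).
#' @param scatter_offset_sd sd of the per-sample additive scatter offset a
#'   (absorbance units).
#' @param baseline_amplitude scale of the smooth per-sample baseline
#'   curvature (absorbance units; degree-2 polynomial with random
#'   coefficients).
#' @param noise_sd sd of the white noise added per point (absorbance).
#' @param seed integer seed; generation is a pure function of the config.
#' @return A `synthetic_config` list.
#' @seealso [generate_spectra()], [benchmark_config()], [paper_scale_config()]
#' @export
synthetic_config <- function(n_samples = 160L,
                             n_wavelengths = 500L,
                             wavenumber_range = c(4000, 10000),
                             analyte_bands = default_analyte_bands(),
                             interferent_bands = default_interferent_bands(),
                             ssc_mean = 13.42, ssc_sd = 1.28,
                             ssc_bounds = c(10.81, 17.13),
                             scatter_slope_sd = 0.10,
                             scatter_offset_sd = 0.05,
                             baseline_amplitude = 0.02,
                             noise_sd = 0.002,
                             seed = 1L) {
  cfg <- list(
    n_samples = check_count(n_samples, "n_samples", 4L),
    n_wavelengths = check_count(n_wavelengths, "n_wavelengths", 8L),
    wavenumber_range = as.numeric(wavenumber_range),
    analyte_bands = as.data.frame(analyte_bands),
    interferent_bands = as.data.frame(interferent_bands),
    ssc_mean = check_number(ssc_mean, "ssc_mean"),
    ssc_sd = check_number(ssc_sd, "ssc_sd", 0),
    ssc_bounds = as.numeric(ssc_bounds),
    scatter_slope_sd = check_number(scatter_slope_sd, "scatter_slope_sd", 0),
    scatter_offset_sd = check_number(scatter_offset_sd, "scatter_offset_sd", 0),
    baseline_amplitude = check_number(baseline_amplitude, "baseline_amplitude", 0),
    noise_sd = check_number(noise_sd, "noise_sd", 0),
    seed = check_count(seed, "seed", 0L))
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  r <- cfg$wavenumber_range
  if (length(r) != 2L || any(!is.finite(r)) || r[1L] >= r[2L])
    stopf("'wavenumber_range' must be (low, high) with low < high")
  b <- cfg$ssc_bounds
  if (length(b) != 2L || any(!is.finite(b)) || b[1L] >= b[2L])
    stopf("'ssc_bounds' must be (low, high) with low < high")
  if (cfg$ssc_mean <= b[1L] || cfg$ssc_mean >= b[2L])
    stopf("'ssc_mean' (%g) must lie strictly inside ssc_bounds (%g, %g)",
          cfg$ssc_mean, b[1L], b[2L])
  for (nm in c("analyte_bands", "interferent_bands")) {
    bd <- cfg[[nm]]
    if (!all(c("center", "width", "intensity") %in% names(bd)))
      stopf("'%s' needs columns center, width, intensity", nm)
    if (nrow(bd) > 0L && any(bd$width <= 0))
      stopf("'%s' has a non-positive band width", nm)
  }
  ib <- cfg$interferent_bands
  if (nrow(ib) > 0L) {
    if (is.null(ib$variation)) stopf("'interferent_bands' needs a 'variation' column")
    if (any(ib$variation < 0 | ib$variation >= 1))
      stopf("'interferent_bands' variation must be in [0, 1)")
  }
  if (nrow(cfg$analyte_bands) == 0L)
    stopf("'analyte_bands' must contain at least one band")
  if (any(cfg$analyte_bands$center < r[1L] | cfg$analyte_bands$center > r[2L]))
    stopf("'analyte_bands' has a center outside wavenumber_range")
  invisible(cfg)
}

#' @rdname synthetic_config
#' @export
default_analyte_bands <- function() {
  # sugar-associated C-H / O-H combination and overtone features; widths
  # keep the SSC information concentrated in a few tens of wavelength
  # points, as in fruit NIR where selection algorithms find compact
  # informative subsets
  data.frame(center = c(4400, 5800, 8300),
             width = c(40, 40, 40),
             intensity = c(0.012, 0.008, 0.004))
}

#' @rdname synthetic_config
#' @export
default_interferent_bands <- function() {
  rbind(water_bands(), minor_constituent_bands())
}

#' @rdname synthetic_config
#' @export
water_bands <- function() {
  # broad water absorption features dominating fruit NIR spectra; water
  # content varies only a few percent between fruit
  data.frame(center = c(5150, 6900),
             width = c(250, 220),
             intensity = c(1.00, 0.65),
             variation = c(0.04, 0.04))
}

#' @rdname synthetic_config
#' @export
minor_constituent_bands <- function() {
  # narrow features from minor constituents (acids, pigments, cell-wall
  # material) whose concentration varies strongly between fruit but is
  # unrelated to SSC: the "uninformative biological variability" that
  # full-spectrum models overfit and wavelength selection removes.
  # Centers avoid the analyte windows of default_analyte_bands().
  data.frame(center = c(4750, 4850, 4950, 5050, 6250, 6350, 6450, 6550,
                        6650, 7050, 7200, 7350, 7500, 7650, 8850, 9000,
                        9150, 9300, 9500, 9700),
             width = 15,
             intensity = 0.06,
             variation = 0.30)
}

#' @rdname synthetic_config
#' @export
benchmark_variability_bands <- function() {
  # fixed pseudo-random placement of 80 single-column uninformative
  # variability features on the 200-point benchmark grid, kept at least
  # two grid steps away from every informative column
  wn <- seq(4000, 10000, length.out = 200L)
  idx <- c(5L, 6L, 7L, 12L, 13L, 15L, 16L, 17L, 18L, 19L, 20L, 21L, 23L,
           24L, 29L, 30L, 31L, 32L, 33L, 35L, 39L, 42L, 47L, 48L, 54L,
           55L, 56L, 59L, 60L, 61L, 72L, 73L, 76L, 77L, 79L, 80L, 81L,
           83L, 85L, 89L, 90L, 91L, 95L, 96L, 98L, 100L, 103L, 104L,
           105L, 109L, 110L, 111L, 112L, 115L, 116L, 119L, 120L, 124L,
           132L, 136L, 137L, 146L, 148L, 156L, 158L, 162L, 163L, 164L,
           166L, 167L, 168L, 172L, 173L, 178L, 183L, 184L, 185L, 188L,
           193L, 195L)
  data.frame(center = wn[idx], width = 12, intensity = 0.08,
             variation = 0.35)
}

#' Preset configurations
#'
#' `benchmark_config()` is the selector benchmark: 160 samples on a
#' 200-point grid with ten narrow analyte bands of equal intensity, each
#' whose support (center +/- 3 width) covers exactly one grid point, so
#' ground truth marks 10 equally informative variables out of 200.
#' `paper_scale_config()` uses the full 3112-point grid of an FT-NIR
#' instrument over 4000--10000 cm^-1.
#'
#' @param seed integer seed.
#' @param ... overrides passed on to [synthetic_config()].
#' @return A `synthetic_config`.
#' @export
benchmark_config <- function(seed = 1L, ...) {
  wn <- seq(4000, 10000, length.out = 200L)
  # band centers sit on grid points well clear of the broad water
  # interferents at 5150 / 6900 cm^-1, so the contrast between
  # informative and null columns is unambiguous; width 8 makes each
  # support (+/- 24 cm^-1) narrower than the 30.15 cm^-1 grid spacing.
  # Equal intensities and a noise level giving per-column SNR ~ 3 mean
  # every informative column contributes to an optimal model, so
  # recovery of the full set is well-posed.
  # besides the water background, medium-width bands with strongly varying
  # per-sample amplitude emulate uninformative biological variability:
  # they carry no SSC information but give full-spectrum PLS spurious
  # finite-sample directions to overfit, which is what wavelength
  # selection is meant to remove
  synthetic_config(
    n_samples = 160L, n_wavelengths = 200L,
    analyte_bands = data.frame(
      center = wn[c(10L, 66L, 70L, 130L, 140L, 150L, 160L, 170L, 180L, 190L)],
      width = 8, intensity = 0.012),
    interferent_bands = rbind(
      water_bands(),
      benchmark_variability_bands()),
    noise_sd = 0.005,
    seed = seed, ...)
}

#' @rdname benchmark_config
#' @export
paper_scale_config <- function(seed = 1L, ...) {
  synthetic_config(n_wavelengths = 3112L, seed = seed, ...)
}

#' Generate a synthetic FT-NIR dataset with known ground truth
#'
#' Draws SSC values from the configured truncated normal, builds each
#' sample's clean spectrum as the sum of SSC-scaled analyte bands and
#' independently varying interferent bands, then corrupts it:
#' `emitted_i = a_i + (1 + b_i) * clean_i + baseline_i + noise_i`,
#' with additive offset `a_i ~ N(0, scatter_offset_sd)`, multiplicative
#' deviation `b_i ~ N(0, scatter_slope_sd)`, a per-sample random degree-2
#' polynomial baseline scaled by `baseline_amplitude`, and white noise.
#' Identical configs (including seed) give bit-identical output.
#'
#' @param config a [synthetic_config()].
#' @return A list with components `spectra` (a [spectra_set()] carrying the
#'   emitted absorbance and the SSC reference values) and `truth` (a
#'   `ground_truth` list with `ssc_true`, `informative_windows` — the
#'   center +/- 3 width supports of the analyte bands —, `scatter_params`,
#'   `clean_spectra`, and the stored `baseline` and `noise` draws, so the
#'   corruption can be reconstructed exactly).
#' @examples
#' out <- generate_spectra(synthetic_config(n_samples = 8, n_wavelengths = 50,
#'                                          seed = 42))
#' out$spectra
#' @export
generate_spectra <- function(config) {
  if (!inherits(config, "synthetic_config"))
    config <- do.call(synthetic_config, as.list(config))
  validate_synthetic_config(config)
  n <- config$n_samples
  p <- config$n_wavelengths
  wn <- seq(config$wavenumber_range[1L], config$wavenumber_range[2L],
            length.out = p)
  with_seed(config$seed, {
    ssc <- rtruncnorm(n, config$ssc_mean, config$ssc_sd, config$ssc_bounds)

    clean <- matrix(0, n, p)
    for (b in seq_len(nrow(config$analyte_bands))) {
      bd <- config$analyte_bands[b, ]
      shape <- exp(-(wn - bd$center)^2 / (2 * bd$width^2))
      clean <- clean + outer(ssc * bd$intensity, shape)
    }
    if (nrow(config$interferent_bands) > 0L) {
      for (b in seq_len(nrow(config$interferent_bands))) {
        bd <- config$interferent_bands[b, ]
        shape <- exp(-(wn - bd$center)^2 / (2 * bd$width^2))
        amp <- runif(n, 1 - bd$variation, 1 + bd$variation) * bd$intensity
        clean <- clean + outer(amp, shape)
      }
    }

    offset <- rnorm(n, 0, config$scatter_offset_sd)
    slope <- rnorm(n, 0, config$scatter_slope_sd)
    # smooth curvature: per-sample quadratic in the scaled axis t in [-1, 1]
    t_ax <- seq(-1, 1, length.out = p)
    bl_coef <- matrix(rnorm(3L * n, 0, config$baseline_amplitude), n, 3L)
    baseline <- bl_coef %*% rbind(1, t_ax, t_ax^2)
    noise <- matrix(rnorm(n * p, 0, config$noise_sd), n, p)

    emitted <- offset + (1 + slope) * clean + baseline + noise

    windows <- cbind(low = config$analyte_bands$center - 3 * config$analyte_bands$width,
                     high = config$analyte_bands$center + 3 * config$analyte_bands$width)

    spectra <- spectra_set(emitted, wn, ssc = ssc, provenance = "synthetic")
    truth <- structure(
      list(ssc_true = ssc,
           informative_windows = windows,
           scatter_params = data.frame(offset = offset, slope = slope),
           clean_spectra = clean,
           baseline = baseline,
           noise = noise),
      class = "ground_truth")
    list(spectra = spectra, truth = truth)
  })
}

# exact truncated-normal draws by rejection
rtruncnorm <- function(n, mean, sd, bounds) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(0L)
  while (length(out) < n) {
    draw <- rnorm(2L * (n - length(out)), mean, sd)
    out <- c(out, draw[draw >= bounds[1L] & draw <= bounds[2L]])
  }
  out[seq_len(n)]
}

#' Column indices of the informative wavelength windows
#'
#' @param truth a `ground_truth` object from [generate_spectra()].
#' @param wavenumbers the wavenumber axis of the matching spectra set.
#' @return Integer vector of column positions lying inside any informative
#'   window.
#' @export
informative_indices <- function(truth, wavenumbers) {
  stopifnot(inherits(truth, "ground_truth"))
  hit <- rep(FALSE, length(wavenumbers))
  for (w in seq_len(nrow(truth$informative_windows))) {
    hit <- hit | (wavenumbers >= truth$informative_windows[w, "low"] &
                    wavenumbers <= truth$informative_windows[w, "high"])
  }
  which(hit)
}
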
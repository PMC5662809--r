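---
title: "NIR calibration of fruit soluble solids: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{NIR calibration of fruit soluble solids: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nircal)
```

## The problem

Soluble solids content (SSC, °Brix) is the sugar-dominated dissolved
fraction of fruit juice and a principal quality attribute of apples and
other fruit. FT-NIR diffuse-reflectance spectroscopy can estimate SSC
non-destructively, but the absorbance spectrum of an intact fruit is
dominated by broad water bands, per-fruit light-scattering differences
(peel, cell structure, path length) and other biological variability
unrelated to sugar. A useful calibration must extract a weak, distributed
sugar signal from underneath all of that. `nircal` implements the whole
calibration chain — pretreatment, sample partitioning, PLS regression
with cross-validated complexity selection, and wavelength selection — and
a synthetic data generator that emulates the statistical structure of
such a study so the chain can be validated against known ground truth.

## Models and procedures

### Pretreatments

All pretreatments operate row-wise (per spectrum) except the
Savitzky-Golay filter, which operates along the wavelength axis:

* **Savitzky-Golay** smoothing fits a polynomial of order $d$ (default 2)
  by least squares in a moving window of $w$ points and replaces the
  centre point by the fitted value. At the spectrum ends the window is
  truncated asymmetrically and the local polynomial refitted, so no
  padding data are invented and the spectrum keeps its length. A
  polynomial of degree ≤ $d$ is reproduced exactly, everywhere.
* **MSC** regresses each spectrum $s$ on a reference spectrum $r$,
  $s \approx a + b\,r$, and corrects to $(s-a)/b$, removing additive
  offsets and multiplicative gain. The reference is the column mean of
  the *calibration* spectra at that position of the chain; prediction
  samples are corrected against the stored reference and never influence
  it. This is the leak-free reading of "the average spectrum of the data
  set"; the alternative (including prediction samples) would let test
  data shape the transform.
* **SNV** centres each spectrum and scales it to unit standard deviation
  (the $n-1$ denominator, stated here so exact tests are possible).
* **Mean normalization** divides each spectrum by its own mean.

Chains are applied in listed order; "S-G and MSC" means smooth first,
then scatter-correct.

### Kennard-Stone partitioning

The calibration subset is grown by the maximin rule on Euclidean
distances between spectra: the farthest pair first, then repeatedly the
sample whose minimum distance to the selected set is largest. Distance
ties are broken toward the lowest sample index, making the procedure
fully deterministic. A useful side effect is that removing the
never-selected samples from the pool does not change the selection — the
basis of the package's no-leakage test.

### PLS with RMSECV-driven complexity selection

The calibration engine is single-response NIPALS PLS on mean-centred
data, without variable scaling (absorbance variables share units).
Each component extracts the weight vector proportional to the covariance
of the residual spectra with the residual SSC. The per-component scores,
loadings and inner coefficients are retained, and collapsed into a single
regression vector $\beta = W(P^TW)^{-1}q$ so that prediction is
$(x - \bar x)\beta + \bar y$; both prediction paths agree to numerical
precision and one is tested against the other. At full rank PLS equals
ordinary least squares, which provides an external oracle.

The number of latent variables is the minimizer of the k-fold RMSECV
(10 folds by default, fold assignment by a seeded round-robin deal, the
centring refitted inside each fold). Residuals are pooled across folds
before the root mean square is taken — with equal fold sizes this is
almost identical to averaging per-fold RMSEs, and pooling keeps the
estimator well-defined for unequal folds. Ties within $10^{-12}$ are
broken toward fewer components. The default ceiling is 14 components with
a hard cap at what the smallest training fold supports.

### CARS

Competitive adaptive reweighted sampling runs $N = 50$ Monte-Carlo
sampling runs. In run $i$: a random 80 % of the calibration samples is
drawn; PLS is fitted on the surviving wavelengths; each wavelength is
weighted by its normalized absolute regression coefficient; an
exponentially decreasing schedule $r_i = a e^{-k i}$ (with $a, k$ fixed by
$r_1 = 1$ and $r_N = 2/p$) enforces keeping only the top
$\lceil p\,r_i\rceil$ by weight; adaptive reweighted sampling then draws
$\lceil p\,r_i\rceil$ times with replacement, weight-proportionally, and
the unique draws survive. Each run's subset is scored by 10-fold RMSECV
on **all** calibration rows (the subsample is only used for the weight
model), and the minimal-RMSECV subset wins.

Two choices deserve a note. First, the ARS draw count follows the
schedule $\lceil p\,r_i\rceil$, not the current subset size: drawing
fewer times (e.g. once per surviving wavelength) makes early retention a
$1-e^{-w}$ lottery that randomly destroys informative wavelengths at
small $p$. Second, the weight model's component count is the
cross-validated choice carried forward from the previous run's scoring
step (initialized by a full-spectrum cross-validation), because a
ceiling-complexity fit overfits and scrambles the coefficient ranking
that both the enforced and the adaptive reduction depend on.

### Random frog

A chain over wavelength subsets. From the current subset $V$, a candidate
size $Q^*$ is drawn from $\mathrm{Normal}(|V|, \theta|V|)$, rounded and
clipped to $[1, p]$. The candidate set is built by deleting the
lowest-weighted members of $V$ or adding the top-weighted outside
wavelengths (weights again |PLS regression coefficients|, at
cross-validated component counts). The candidate is accepted with
probability $\min(1, \mathrm{perf}^*/\mathrm{perf})$ where perf is
1/RMSECV. The selection probability of wavelength $j$ is the fraction of
iterations whose accepted subset contained $j$; wavelengths with
SP ≥ 0.05 are selected. The acceptance rule, candidate construction and
the defaults $Q = 2$, $\theta = 0.3$ follow the established random-frog
literature; the test-scale default is $N = 1000$ iterations (10 000 at
full scale), a balance between chain averaging and runtime — shorter
chains leave visibly noisy SP values.

### Evaluation

$R^2$ is the squared Pearson correlation between measured and predicted
values (the convention behind calibration/prediction correlation
coefficients); `r2_method = "ssr"` switches to $1 - SSE/SST$, which
penalizes bias and mis-scaling and can be negative. RMSE uses the plain
$n$ denominator; bias is the mean signed error.

## The synthetic data generator

`generate_spectra()` simulates a 160-sample study on a uniform
wavenumber grid (500 points over 4000–10000 cm⁻¹ by default; a
3112-point "paper-scale" preset exists, and 500 points keeps the test
suite fast while preserving all structure). Reference SSC is drawn from
N(13.42, 1.28²) truncated by rejection to [10.81, 17.13] °Brix —
descriptive statistics typical of a commercial apple batch. Note the
*sample* standard deviation of a truncated draw (~1.15) is smaller than
the nominal σ; the generator parameterizes the parent distribution.

Each clean spectrum is a sum of Gaussian absorption bands (any smooth
unimodal shape would do; Gaussians have closed-form support):

* **Analyte bands** at 4400, 5800 and 8300 cm⁻¹ (sugar-associated C-H and
  O-H combination/overtone regions), width 40 cm⁻¹, amplitudes
  proportional to the sample's SSC (0.012, 0.008, 0.004 AU/°Brix). The
  deliberately narrow widths keep the SSC information concentrated in a
  few tens of grid points, the regime in which wavelength selection has
  something to find.
* **Water bands** at 5150 and 6900 cm⁻¹ (widths 250/220, amplitudes
  1.0/0.65 AU) with only ±4 % per-sample amplitude jitter — water
  dominates the spectrum but varies little between fruit.
* **Minor-constituent bands**: twenty narrow features (width 15, 0.06 AU)
  with ±30 % per-sample amplitude jitter, independent of SSC. These
  embody *uninformative biological variability* — real structure that a
  full-spectrum model can overfit and that wavelength selection should
  discard.

The emitted spectrum of sample $i$ is
$a_i + (1+b_i)\,\mathrm{clean}_i + \mathrm{baseline}_i + \varepsilon_i$
with additive scatter offset $a_i \sim N(0, 0.05)$, multiplicative
deviation $b_i \sim N(0, 0.10)$, a per-sample random quadratic baseline
(coefficients $\sim N(0, 0.02)$ over a normalized axis) and white noise
($\sigma = 0.002$ AU). The scatter and baseline magnitudes are package
choices — typical of diffuse-reflectance FT-NIR on intact fruit, and
large enough that scatter correction demonstrably matters; no published
values exist for them. All draws are stored in the returned ground truth
so the corruption is exactly reconstructable, and generation is a pure
function of the config including its seed.

Under these defaults the full-spectrum S-G+MSC model reaches
R²_P ≈ 0.93–0.96 and RMSEP ≈ 0.20–0.30 °Brix, and scatter-corrected
pretreatments beat raw spectra — the qualitative structure of published
apple SSC calibrations.

### The selector benchmark

`benchmark_config()` is a harder, exactly-labelled instance for validating
wavelength selection: 200 grid points of which exactly **10** carry SSC
signal (ten single-column analyte bands of equal intensity, widths
narrower than the grid spacing, placed away from the water bands so the
informative/null contrast is unambiguous), plus **80** single-column
minor-constituent features with ±35 % amplitude jitter and per-point
noise giving the informative columns an SNR around 3. Equal intensities
and independent noise mean an optimal model uses *all ten* informative
columns, so "recover the informative set" is well-posed; the 80
uninformative-variability columns are what make full-spectrum PLS
genuinely beatable. What passing benchmarks shows — and what it does not:
the generator produces linear, Gaussian-band spectra; real fruit add
nonlinear scattering, temperature-dependent water-band shifts and
instrument drift, none of which are modelled, so these tests validate the
algorithms, not instrument-level performance claims.

## Numerical choices and degenerate inputs

* NIPALS stops early if the residual covariance collapses (exactly
  collinear data); later components are zero and predictions stop
  changing, which keeps cross-validation defined at every requested
  component count.
* Distance and weight ties (Kennard-Stone, CARS, random frog) break
  toward the lowest index: determinism without hidden randomness.
* MSC with a fitted slope of exactly zero, SNV on a constant spectrum and
  mean normalization on a zero-mean spectrum raise errors naming the
  offending sample.
* A CARS run whose surviving set drops below two wavelengths is recorded
  with RMSECV = ∞ and can never be the winning run; the working set is
  not updated past that point.
* Random-frog candidates that cannot be cross-validated are rejected;
  proposals clip to $[1, p]$.
* All stochastic stages draw their randomness under a locally-seeded RNG
  scope that restores the caller's RNG state, so identical configs give
  bit-identical results regardless of the surrounding program.

## Known limitations

* Single-response PLS only; no PCR/SVM baselines.
* The S-G edge convention (truncated asymmetric windows) matches no
  specific commercial implementation; interior points agree with any
  standard implementation and are cross-checked against `signal`.
* RMSECV surfaces over wavelength subsets are shallow near the optimum,
  so CARS's winning subset size varies noticeably between seeds — an
  intrinsic property of the method, not an implementation artifact.
* The generator's interferent amplitudes are uniform draws; real
  constituent variation is likely correlated across bands.
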
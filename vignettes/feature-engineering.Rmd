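---
title: "Feature engineering and stacked regression for Vis-NIR SSC prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feature engineering and stacked regression for Vis-NIR SSC prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specstack)
```

## The problem

Soluble solids content (SSC, % Brix) is the standard refractometric sugar
proxy used to grade fruit. Visible/near-infrared reflectance spectra
(here 450-1000 nm) carry SSC information through O-H and C-H overtone
absorption, but raw spectra are corrupted by multiplicative scatter,
baseline drift, between-sample variation and instrument noise, and
adjacent wavelengths are highly redundant. A working calibration therefore
needs two feature-engineering decisions before any regression: how to
pre-process the spectra, and which wavelengths (or projections) to feed
the model. `specstack` implements both menus in full, evaluates every
combination under one fixed protocol, and adds a two-base stacked
generalization on top.

The downstream model is deliberately plain ordinary least squares: the
point of the package is to isolate the effect of feature engineering, not
to tune a learner.

## Evaluation protocol

The dataset is split once by SPXY (sample-set partitioning based on joint
X-Y distances): with the joint distance
$d(i,j) = d_x(i,j)/\max d_x + d_y(i,j)/\max d_y$, the most-distant pair
seeds the calibration set and the remaining calibration members are added
by the Kennard-Stone max-min rule until the 3:1 calibration:prediction
ratio is reached (87/29 for 116 samples). All pipelines share that split.

Each pipeline is scored twice:

* **Calibration (cross-validation) triple** `rmse_c`, `mape_c`, `rpd_c`:
  seeded 5-fold cross-validation on the calibration set. Supervised steps
  (DOSC and every selector) are refitted inside each fold so no held-out
  fold information reaches them; reported values are means across folds,
  and each fold's RPD uses that fold's own sample SD.
* **Prediction triple** `rmse_p`, `mape_p`, `rpd_p`: a single fit on the
  whole calibration set applied once to the untouched prediction set.

The metrics are $\mathrm{RMSE} = \sqrt{\tfrac1N \sum_i (y_i-\hat y_i)^2}$,
$\mathrm{MAPE} = \tfrac1N \sum_i |y_i-\hat y_i|/y_i$ (a fraction), and
$\mathrm{RPD} = \mathrm{SD}/\mathrm{RMSE}$. SD is the *sample* standard
deviation (denominator $N-1$) of the measured values of the evaluated set;
the $N-1$ convention is a package decision — the convention cannot be
recovered from printed study tables, whose SD/RMSE/RPD triples are not
exactly self-consistent — and it makes `rpd * rmse == sd(y)` an exact
identity the tests assert. MAPE requires strictly positive responses,
which SSC always satisfies.

Whether a study of this design fits its selectors once on the whole
calibration set before cross-validating (a leaky shortcut) is usually
impossible to tell from a published methods description. The package
defaults to the
conservative per-fold protocol; `cv_evaluate(..., leaky = TRUE)` exists
only to quantify the difference, and a test asserts the leaky variant
reports an equal or rosier calibration error.

## Pre-processors

Four methods plus the identity, all row-count and column-count preserving:

* **SNV** standardizes each spectrum to mean 0, sample SD 1 (denominator
  $p-1$, documented so tests are exact). Removes per-sample gain and
  offset; idempotent and affine-invariant by construction.
* **DC (detrend)** subtracts a per-spectrum least-squares polynomial in
  wavelength, degree 1 by default ("trend lines"); exactly annihilates
  planted linear drift.
* **SG (Savitzky-Golay)** smooths with a moving-window polynomial fit,
  window 11 and order 2 by default (the study does not state its values;
  both are configurable). Edges use the boundary rows of the SG projection
  matrix. An interpolating order (window 5, order 4) is the identity,
  which the tests use as an exact check.
* **DOSC (direct orthogonal signal correction)** is the one supervised
  pre-processor. The cited literature does not spell out the algorithm, so
  the package implements the standard direct construction: column-center
  X and center y; anti-project the centered spectra on the response;
  take leading principal-component scores of that response-free matrix;
  derive deflation loadings $p_k = X_c^\top t_k / (t_k^\top t_k)$ and
  minimum-norm weights solving $X_c w_k \approx t_k$ so prediction spectra
  can be corrected without their responses. One component is removed by
  default (`n_osc = 1`, unstated in the study and configurable). For
  spectral shapes ($p > n$) the training scores are orthogonal to the
  centered response to machine precision, which is asserted at 1e-6
  relative tolerance.

## Selectors

Nine methods under one fit/apply contract (`spectral_selector` objects;
applying never refits):

* **Projections** — PCA (centered covariance eigenvectors), SVD (right
  singular vectors of the uncentered matrix), KPCA (centered RBF kernel
  with inverse length-scale $1/p$; kernlab supplies the decomposition and
  the out-of-sample extension). A linear-kernel option exists solely so a
  test can confirm KPCA degenerates to PCA. With the smooth, highly
  collinear spectra this package targets, the RBF kernel matrix is close
  to singular; when it supports fewer components than the requested
  maximum, the cross-validated search simply stops at the achievable
  count.
* **Rankers** — univariate F-test ($F = (n-2)r^2/(1-r^2)$), absolute
  Pearson correlation, and a k-nearest-neighbour mutual-information
  estimate (Kraskov algorithm 1, $k = 3$, tiny seeded jitter on duplicate
  values). Constant columns score 0 with a warning rather than erroring,
  so a degenerate wavelength cannot kill a grid run. Ties break toward
  the lower wavelength index, making top-n sets nested and deterministic.
* **Iterative searchers** — RFE (standardize columns, repeatedly drop the
  smallest-|coefficient| OLS term; deterministic), SPA (for every start
  wavelength grow a chain by maximal residual norm under successive
  orthogonal projection, then score every (start, length) candidate by
  internal 5-fold OLS RMSE), and CARS (Monte-Carlo competitions driven by
  normalized |PLS coefficient| weights, the exponential decay function
  $r_i = a e^{-ki}$ with $r_1 = 1$ and $r_N = 2/p$, and adaptive
  reweighted resampling; the retained set with minimal 5-fold PLS RMSECV
  wins). CARS run count (50), Monte-Carlo ratio (0.8) and PLS component
  cap (10) are unstated in the study and exposed as configuration.

CARS is the only place PLS appears; a compact internal SIMPLS provides its
coefficients and RMSECV, and a unit test pins it against an independent
PLS implementation. SPA candidates are scored with OLS, not PLS, for
consistency with the downstream model.

How many features? Rankers, projections and RFE search
$n \in 1..\min(30, \text{fold size} - 2)$ by mean fold RMSE (RFE is not
assigned to either camp by the protocol description; since its
elimination order yields nested subsets for free, it joins the CV search).
SPA and CARS size their subsets internally.

## The experiment grid and tally

`run_grid()` crosses all 5 pre-processing options with all 10 selection
options against one shared split and fold seed: 50 result rows. A master
seed fans out to per-component seeds by stable name hashing, so adding a
method never changes any other method's random stream. Failures (e.g. a
numerically degenerate regression) become `failed = TRUE` rows with a
reason, never errors, mirroring how such a cell would appear as "/" in a
published table.

`best_frequency()` awards, within each pre-processing group, one count per
metric to the best non-failed selection method — six counts per group
(three cross-validated calibration metrics, three prediction metrics).
Comparisons use full floating precision, not table rounding; exact ties
warn and break by the canonical method order. Every complete group row
therefore sums to 6 and a full grid totals 30. `selection_helps()` flags,
per group, the selectors that beat the no-selection baseline on both RMSE
columns.

## Stacked generalization

Two base pipelines — by default detrend+CARS (strong calibration fit) and
SG+CARS (strong generalization) — are combined by an OLS meta-model over
their two prediction columns only. The protocol description of stacking
does not say how the meta-model avoids refitting bias; the package adopts
the standard remedy: base predictions used for meta training are strictly
out-of-fold under a shared seeded 5-fold partition of the calibration set,
after which the bases are refitted on the full calibration set. The meta
solve is minimum-norm, so even identical bases yield a well-defined stack
(the weight splits evenly and predictions match a single-base meta
exactly). The stack's calibration triple in `stack_evaluate()` comes from
an outer cross-validation around the entire stacking procedure — the
honest analogue of the per-pipeline cross-validated triple; the cheaper
alternative of reusing the meta's in-sample fit on out-of-fold predictions
was rejected because it reuses each calibration row once.

## The synthetic generator

No spectral dataset is distributed with the package (none is publicly
deposited for the motivating application), so `generate_spectra()` is a
first-class module that emulates the data structure the analysis assumes,
with planted ground truth:

* SSC is normal with mean 13.148 and SD 1.025 % Brix (truncated to
  positive), matching the distribution reported for the 116-fruit study
  the defaults mirror.
* Each clean spectrum is a logistic continuum ramp (low reflectance at
  450 nm, plateau near 780 nm, smoothly damped below 500 nm) minus
  Gaussian absorption bands at 600, 680, 840 and 960 nm whose depths are
  affine in standardized SSC. Band positions follow the reported
  concentration of informative features around 600-700 nm and above
  750 nm; widths (25-35 nm) and depths (0.08-0.12) are plausible for
  liquid-water-dominated fruit tissue. The continuum-damping below 500 nm
  reproduces the narrow-then-broad variance profile of the real
  reflectance distribution.
* Disturbances, applied in `apply_disturbances()`: log-normal per-sample
  gain (scatter; log-SD 0.08), linear baseline drift (offset SD 0.02,
  slope SD 0.03), i.i.d. noise (SD 0.005), and smooth sample-specific
  spectral variation (squared-exponential in wavelength, SD 0.05 of the
  continuum level, correlation length 15 nm). The last term represents
  between-fruit differences unrelated to SSC. It matters more than it
  looks: with only gain, drift and white noise, a minimum-norm regression
  on all 221 channels can average the noise away and no selector can beat
  it; smooth high-rank sample variation is what makes full-spectrum OLS
  overfit — as it does on real spectra — and wavelength selection
  worthwhile. Amplitudes were fixed once so that cross-validated RPD of
  selected-wavelength pipelines lands in the 0.8-1.4 range typical of
  fruit SSC calibrations.
* Ground truth (informative band centers, nearest grid indices, seed and
  config echo) travels with the dataset and in a sidecar JSON next to the
  wide CSV writer, so selector-recovery tests need no stored fixtures.

What passing tests on this generator do **not** show: radiative-transfer
realism, hyperspectral image handling (spectra are per-sample vectors; the
extraction of per-fruit spectra from image cubes is explicitly not
modeled), or that any particular pipeline would win on real kiwifruit
data. The planted signal is rank-1 — every band depth follows the same
standardized SSC factor — so a single well-chosen wavelength can carry all
of it; this is why the cross-validated feature count is sometimes 1 and
why recovery tests ask for band *neighborhoods*, not exact indices.

## Numerical choices

* OLS uses a QR solve when the design has full column rank and a
  minimum-norm SVD pseudoinverse otherwise, so the $q > n$ "no selection"
  grid cells are well-defined instead of crashing.
* SPXY, SPA, RFE and the rankers are exactly deterministic; CARS, MI and
  all fold assignments are seeded. One master seed reproduces an entire
  grid bit-for-bit.
* Tally comparisons use full floating precision; ties (which would be
  invisible at 3-decimal rounding) warn explicitly.
* DOSC guards the degenerate case where nothing orthogonal to the
  response remains (a zero component rather than 0/0).
* Metric edge cases: RMSE 0 reports RPD as infinite with a warning; a zero
  or negative measured value is an error because MAPE divides by it.

## Problem sizes used by the test suite

Unit tests run on 8-60-sample datasets with full or coarsened wavelength
grids; oracle comparisons use $p \le 6$ so exhaustive enumeration stays
exact. The acceptance checks run at the study scale the defaults emulate —
116 samples by 221 wavelengths — including one full 50-cell grid and
20-replicate recovery, scatter-correction and stacking studies with the
canonical seed sets 1..20.

## A worked example

```{r, eval = FALSE}
library(specstack)

dataset <- generate_spectra(generator_config(seed = 1))
split <- spxy_split(dataset, "3:1")

grid <- run_grid(dataset, seed = 1)
best_frequency(grid)

stacked <- stack_evaluate(dataset, split, seed = 1)
stacked[, c("model", "rmse_c", "rmse_p", "rpd_p")]
autoplot(best_frequency(grid))
```

## Known limitations

* The generator's signal is linear in standardized SSC by design (the
  downstream model is linear); MI's advantage over correlation-based
  rankers therefore rarely shows on default synthetic data, and is tested
  on a constructed quadratic instead.
* KPCA near the RBF kernel's flat limit behaves like PCA, so on this data
  the two seldom differ materially — consistent with how close their
  published performance tends to be.
* CARS subset sizes on easy, low-noise synthetic data can be much larger
  than the 8-18 wavelengths typical for real spectra; the RMSECV minimum
  is simply flat there.
* `stack_evaluate()`'s outer CV refits both CARS bases per outer fold and
  is the most expensive call in the package; `calibration = "none"` skips
  it when only prediction-set behavior matters.
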
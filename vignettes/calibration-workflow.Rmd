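---
title: "Estimating leaf chlorophyll from vis/NIR spectra: models and design choices"
author: "chlorospec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating leaf chlorophyll from vis/NIR spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Chlorophyll concentration (mg per g fresh weight) is the standard proxy for
leaf photosynthetic capacity and for plant stress status. Wet-chemistry
determination (solvent extraction, spectrophotometry) is accurate but
destructive and slow. Visible/near-infrared reflectance spectroscopy
(350--2500 nm) offers a non-destructive alternative, provided a
multivariate calibration links the spectrum to the lab value. The quality
of such a calibration depends critically on *which* samples receive the
expensive wet-chemistry reference measurement.

`chlorospec` implements that whole workflow for a multi-species,
multi-month leaf campaign:

1. reflectance is converted to absorbance, `A = log10(1/R)`, and smoothed
   with a Savitzky--Golay filter;
2. a calibration pool is split off by the Kennard--Stone max--min
   algorithm;
3. nested candidate calibration subsets are compared to the validation
   population with an MSD statistic built on kernel density estimates of
   principal-component scores — the smallest subset that still mirrors the
   population is nominated for wet chemistry;
4. chlorophyll is calibrated on the nominated subset by partial least
   squares regression (PLSR) and by a Cubist-style rule-based model, and
   judged on the held-out validation samples with R², RMSEP, RPIQ and
   bias.

Because the field data such campaigns produce are rarely public, the
package carries a synthetic generator that emulates the campaign's
statistical structure, so every stage is exercisable and testable from
code alone.

## Preprocessing

Absorbance linearises the concentration--signal relation (Beer--Lambert
heuristic); smoothing suppresses instrument and illumination noise. The
defaults — first-order polynomial, 15-band window — are the common setting
for portable field spectrometers. Smoothing is strictly per-spectrum
(row-wise) and requires a uniform wavelength grid; irregular grids are a
hard error rather than a silent resample. Edge handling defaults to
evaluating the boundary window's polynomial at the edge positions
(`edge = "poly"`), so no bands are discarded; a shrinking symmetric window
is available as `edge = "shrink"`. Missing cells are never imputed: any
non-finite value is an error, because the density estimates and
regressions downstream assume complete matrices.

The filter is delegated to `signal::sgolayfilt()`, whose boundary
treatment is exactly the polynomial-fit extension; the test suite checks
it against a brute-force per-window least-squares oracle.

## Kennard--Stone selection

`kennard_stone()` starts from the two mutually most distant samples
(Euclidean distance) and repeatedly adds the sample maximising the minimum
distance to those already chosen. Ties break to the lowest row index, and
the initial pair to the lexicographically smallest pair, making the
algorithm fully deterministic. Selection runs in the principal-component
space retaining 99 % of the spectral variance rather than on the raw
2151-band spectra: the PC basis removes the noise floor and makes
distances meaningful; `--space raw` behaviour is available by passing raw
matrices. Because one selection run's prefixes are themselves valid
selections, `nested_subsets()` draws all candidate subset sizes from a
single run, so the subsets are nested by construction.

## The MSD representativeness statistic

For subset *ss* and validation population *p*, and each retained component
*j*, two Gaussian kernel density estimates are formed on a shared grid and
with a *shared* bandwidth, and compared by the squared Euclidean distance

d²_j = ∫_a^b ( P_p(x_j) − P_s(x_j ∈ ss) )² dx_j ,

with the MSD the mean of d²_j over the k components (default k = 6). A
small MSD means the subset's score distribution matches the population's —
the subset is representative.

Numerical choices, all configurable:

* **Bandwidth**: Silverman's rule-of-thumb computed on the *population*
  scores, then reused for the subset density. A shared bandwidth makes d² a
  pure distribution comparison; estimating bandwidths separately would
  confound subset size with kernel width.
* **Integration range**: the union of both score ranges padded by 3
  bandwidths; beyond that the Gaussian tails contribute below the grid
  resolution.
* **Grid**: 512 equally spaced points; the trapezoid rule on smooth KDE
  pairs is accurate to well below 1e-6 there (doubling the grid moves d²
  by less than 1e-6, and the single-kernel case reproduces the closed-form
  Gaussian overlap integral to machine precision).
* **KDE evaluation** is direct summation, not FFT binning, precisely so
  those identities hold exactly.
* **No leakage**: the PCA is fit on the calibration spectra only;
  validation samples are projected with the calibration loadings.
* **Nomination rule**: the smallest size whose MSD is within 10 %
  (relative) of the sweep minimum. Field studies typically nominate the
  elbow of the MSD curve by eye; an explicit rule replaces eyeballing and
  makes the choice deterministic and testable.

## PLSR with LOO-selected components and VIP

`fit_plsr()` implements NIPALS PLS1 on mean-centred predictors. Variance
scaling is deliberately off — all bands share units, the spectroscopy
convention. The latent-variable count minimises the leave-one-out
cross-validated RMSE over 1..20 (exact LOO is affordable at calibration
sizes of a few hundred), after which the model is refit on all rows.
No dedicated chemometrics PLS package ships with a standard R
installation, so the algorithm is implemented natively (~80 lines); the
test suite cross-checks its predictions against an independent PLS
implementation (`mixOmics`) to 1e-10.

Variable importance in projection is

VIP_j = sqrt( p · Σ_a SS_a (w_ja/‖w_a‖)² / Σ_a SS_a ),

with SS_a the response variance captured by component *a*. Mean squared
VIP is identically 1, so VIP > 1 marks bands carrying more than their
share of signal; `important_bands()` turns the VIP spectrum into merged nm
intervals. On the synthetic campaign these intervals cover the green/red
chlorophyll region (500--640 nm) and the red-edge/NIR shoulder
(740--1100 nm) by construction of the generator, plus the water bands that
correlate with nothing and are flagged only when they help the fit cancel
the water nuisance.

## Cubist-lite

`cubist_lite()` re-implements the published Cubist mechanism — it is not a
bit-compatible clone of the proprietary code. Three design points deserve
explanation because the obvious variants fail in measurable ways:

* **Split criterion.** Nodes split where the summed squared error of *two
  per-side simple linear regressions* on the candidate feature drops most.
  A conventional mean-based variance-reduction criterion cannot locate a
  symmetric kink in a piecewise-linear relation (both sides keep equal
  means, so the apparent gain at the kink is zero); the per-side-regression
  criterion finds it exactly, at unchanged asymptotic cost (five running
  sums per candidate feature).
* **Predictor screening.** With thousands of collinear bands, leaf-level
  least squares needs a small, *diverse* predictor set. Features are
  ranked by sequential variance reduction: each pick is the band most
  correlated with the residual of the model on the bands already picked
  (greedy forward selection, default 50). Ranking bands independently
  instead selects 50 near-copies of the single best band and the leaf
  models collapse (validation RMSE degrades by more than an order of
  magnitude on the synthetic campaign). Split candidates are restricted to
  the screened set, which also guarantees every path feature is available
  to every leaf model.
* **Smoothing.** A branch prediction is blended with its parent's linear
  model by inverse estimated error variance, where each model's training
  MSE is inflated by the classic M5 penalty (n + ν)/(n − ν) (ν = fitted
  parameters). This is self-calibrating: exact subtrees (piecewise-linear
  data) keep weight ≈ 1, while small noisy leaves defer to their
  ancestors. Fixed blending weights do one of those two jobs badly
  whichever value is chosen.

Committees follow the residual-reflection scheme: member *m + 1* trains on
`y_adj = y − (ensemble_m(X) − y)`, and the ensemble predicts the mean over
members. The instance-based correction averages, over the k nearest
training samples, `y_i + model(x) − model(x_i)`, and the final output
averages that with the raw model prediction (weight `w_nn = 0.5`); `k = 0`
disables it. The hyperparameter grid — committees {2, 4, 6, 8} ×
neighbours {10, 20, 30, 40} — is searched under 10-fold cross-validation
with one fixed, seeded fold partition shared by all 16 cells; committees
are nested, so each fold fits the largest ensemble once and scores every
cell from prefixes.

## The synthetic campaign generator

`simulate_leaf_dataset()` emulates a five-species, ten-month (February--
November), seven-replicate design — 350 samples on the 350--2500 nm, 1 nm
grid. Chlorophyll is drawn per sample as

chl = species_mean × (1 + 0.15 · cos(2π (month − 8)/12)) + N(0, 0.25²),

clipped to the observed field range 0.79--3.03 mg/g. The species means
(1.47, 1.95, 1.88, 1.10, 1.77 mg/g) and the clip range reproduce published
field statistics for this kind of campaign; the seasonal cosine peaks in
August. The amplitude 0.15 and replicate noise 0.25 mg/g were chosen once,
by matching the implied population mean (≈1.67) and standard deviation
(≈0.47) to the field values 1.57 and 0.46 analytically — not by adjusting
against test outcomes.

Absorbance is additive: a smooth seeded spline baseline per species (one
species deviates over 1200--2400 nm, mimicking a thick-cuticle evergreen),
a chlorophyll-proportional Gaussian band at 600 nm (σ = 45 nm), a
chlorophyll-proportional red-edge/NIR shoulder over 740--1100 nm,
per-sample water bands at 1450 and 1940 nm, and iid N(0, 0.005²) noise;
reflectance is `10^(−A)`, which is in (0, 1] by construction. A
`water_chl_cor` knob can correlate the water index with chlorophyll to
study that confounding.

What the generator does *not* emulate — and therefore what passing tests
do not show about field data: radiative-transfer physics (no leaf
structure or scattering model), detector splice artifacts, correlated
(non-iid) instrument noise, and any nonlinearity between absorbance and
concentration. The signal is linear in chlorophyll by construction, which
is the regime where full-spectrum PLSR is close to an oracle; rule-based
models shine on field data precisely where that linearity breaks down, a
behaviour desk-scale synthetic data cannot reproduce.

## Problem sizes and reproducibility

The shipped tests run the complete workflow at the study scale (350 × 2151,
exact LOO at n ≈ 200, the full 16-cell Cubist grid under 10-fold CV) once,
plus twenty replicate MSD sweeps and a battery of small oracle checks;
fast variants use a 12-sample, 200-band design. All stochastic stages
derive their streams from a single root seed through named substreams, so
rerunning a pipeline with the same seed reproduces every report byte for
byte, and inserting or skipping a stage does not perturb the others.

## Known limitations

* Validation of the nominated subset uses the same validation set that
  defines the MSD target distribution; this mirrors common practice but
  means the MSD criterion is not itself cross-validated.
* The Cubist-lite grid search selects by CV RMSE with deterministic tie
  breaks (fewer committees, then fewer neighbours); no one-standard-error
  rule is applied.
* `read_spectra()` handles wide/long CSV only; proprietary instrument
  binaries, radiometric calibration and detector splice correction are out
  of scope.
* The bias/MBE pair is reported under the single convention
  mean(predicted − observed); literature is inconsistent about the sign,
  so both fields carry the same signed value rather than imitating any
  particular mixture of conventions.
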
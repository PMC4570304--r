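---
title: "Predicting soil total nitrogen from Vis-NIR spectra: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting soil total nitrogen from Vis-NIR spectra: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcmcs)
```

This vignette explains the models the package implements, the choices
made where the method leaves room, and what the synthetic-data tests do
and do not demonstrate about real soil spectra.

## The calibration problem

Soil total nitrogen (TN, mg·kg⁻¹) is expensive to measure chemically but
leaves spectral traces across the visible/near-infrared range
(350–2500 nm). A calibration model maps a reflectance spectrum — here
2151 bands on a uniform 1 nm grid — to TN. Two obstacles dominate:

* **Burr noise.** Field spectra carry high-frequency noise whose
  amplitude varies along the wavelength axis (detector and atmospheric
  effects grow toward the SWIR). Smoothing removes it, but any fixed
  smoothing depth is a global compromise: too shallow leaves noise, too
  deep flattens narrow diagnostic absorptions.
* **Nonlinearity.** Absorption-feature depth saturates with increasing
  analyte content, so the spectrum-to-TN inverse is nonlinear and a
  purely linear regression leaves structured residuals.

The LCMCS pipeline attacks the first problem with per-band smoothing
depth selection (LCM) and the second with a neuro-fuzzy regressor on PLS
latent variables (CS).

## Local correlation maximization

Each (possibly transformed) spectrum is decomposed with a multilevel
discrete wavelet transform (Symlet-8, five levels, symmetric boundary
extension) and reconstructed with the detail coefficients at scales
1..k zeroed, giving a smoothed version at every level k; level 0 is the
untouched input. For each band, the level whose values across the
calibration samples correlate most strongly (in absolute value) with TN
is retained. The retained signed correlations form the optimal
correlative curve (OCC); the retained band values, assembled band-wise,
form the optimal spectrum (OSP).

Interpretation and choices:

* "Decomposition level k" means approximation-only reconstruction —
  progressively smoothed spectra — not coefficient thresholding, for
  which no rule is specified anywhere in the method's description.
* Ties in |r| break toward the **lowest** level: when smoothing buys
  nothing, detail is kept.
* The level map and the band mask are learned on the **calibration set
  only** and applied frozen to validation spectra
  (`apply_level_map()`); `leaky_occ = TRUE` reproduces the pooled
  variant for comparison, since descriptions of this step are often
  ambiguous about the sample set.
* The per-band argmax over six candidate levels inflates the winning
  calibration correlation (a winner's-curse effect of roughly the width
  of the null distribution, ~0.1 at n = 150). This is inherent to the
  method; it is why OCC-selected band counts are larger than fixed-level
  counts at the same significance threshold.
* Boundary handling is symmetric (half-point) extension. One consequence
  worth knowing: a smoothed spectrum re-decomposed at the same depth has
  exactly zero detail only away from the edges; within one filter length
  of an edge the extension breaks the projection property. All
  assertions on "smoothness" therefore look at interior coefficients.

The maximum feasible depth is `floor(log2(n_bands / (filter_len - 1)))`
(7 for 2151 bands with the 16-tap sym8 filter); requesting more is an
error. The wavelet code was verified coefficient-for-coefficient against
an independent reference implementation of the same transform, and the
round trip reproduces inputs to ~1e-12.

## Spectral transforms

`REF` (reflectance), `FDR` (first derivative, central differences with
one-sided edges, per nm), `LOG_INV` (log10(1/R)) and their composition
`FDR_LOG_INV`. Central differences keep the band grid intact, so band
indices remain aligned with wavelengths, and are exact for affine
spectra; base-10 logarithms are the chemometric convention, and every
downstream correlation is invariant to the base. Differentiating per nm
rather than per index only rescales by the constant grid step, which no
correlation-based stage can see.

## Band selection

Bands pass either a fixed absolute-correlation cutoff (e.g.
|r| > 0.40) or a significance rule: |r| above the exact critical value
obtained by inverting the t transform `t = r sqrt((n-2)/(1-r^2))` at the
two-sided level alpha (0.2097 at n = 150, alpha = 0.01; the test suite
checks this against a 100,000-replicate Monte-Carlo null). Selection is
sign-agnostic; no multiple-testing correction is applied across the 2151
bands, deliberately reproducing standard practice for this method family.

## Partial least squares

NIPALS with X-deflation and mean-centring of X and y. With a univariate
response the Y-side scores are the successively deflated responses, the
inner coefficients regress them on the X-scores, and Y-deflation is
redundant. The composite coefficient vector `beta = W (P'W)^{-1} q`
reproduces the deflation recursion to 1e-10 and the full-component fit
equals ordinary least squares on full-rank designs; predictions match an
independent PLS implementation to 1e-8 on random instances. Latent
scores for new spectra are `(x - x_mean) W (P'W)^{-1}`.

The component count can be pinned (the reference comparison models use
5 and 8 latent variables; 5 are passed to the ANFIS) or chosen by
calibration error with a relative-improvement stopping rule
(`choose_components()`, default tolerance 1e-6). Calibration RMSE
decreases strictly even on pure noise, so the default tolerance
effectively selects the feasible maximum; a coarse tolerance (say 0.05)
is the practical way to stop early. Validation-based or cross-validated
selection is intentionally not used, matching the method description.

## ANFIS

A first-order Takagi–Sugeno system on the PLS scores: generalized bell
memberships `1/(1 + ((x-c)/a)^(2b))` per input (two per input by
default), rules as the full grid of membership combinations (32 rules
for 5 inputs), product firing strengths, normalisation across rules,
linear consequents, summed output. Initial centres spread evenly over
each input's training range, widths at half the centre spacing, shape
b = 2.

Hybrid training alternates (i) a global least-squares solve for all
consequent parameters with premises frozen and (ii) one gradient step on
the premise parameters (analytic gradient, verified against finite
differences), with step-halving whenever a step would increase the
training loss, so the loss trace is non-increasing. Widths and shapes
are clamped positive.

**The consequent solve is the numerically delicate step.** With 32 rules
and 6 parameters each, the design has 192 columns against 150
calibration rows — always rank-deficient. An (essentially)
unregularised solve interpolates the calibration targets and
extrapolates wildly on validation scores; in design experiments the
validation R² of an interpolating fit occasionally collapsed far below
zero. The package therefore solves the ridge-regularised problem with
the penalty chosen by 5-fold cross-validation over a grid spanning the
design's singular spectrum (floor 1e-8), selected on the first epoch and
held fixed thereafter. Two properties follow: an exactly representable
target — anything linear in the inputs — drives the cross-validation
error to zero at the floor, so one least-squares pass still fits a
linear target to numerical precision from any premise initialisation;
and on noisy targets the fitted surface stays smooth enough to
generalise. PLS scores are standardised by calibration mean and standard
deviation before entering the network so that widths and penalties act
on comparable scales. Training defaults: 100 epochs, learning rate 0.01,
early stop after 20 non-improving epochs.

## Evaluation

R² (about the evaluated split's own mean — also for validation, where
conventions differ), RMSE in mg·kg⁻¹, and mean relative error as a
percentage, reported per split and per site with an overall block.
Sites with fewer than two samples get explicit NA rows; an empty split
is reported as n = 0 rather than omitted. Calibration/validation splits
are stratified by site; three sites of 100/95/85 samples receive the
reference 55/50/45 calibration allocation, anything else a
largest-remainder proportional allocation.

## The synthetic generator

No public dataset accompanies the method, so the package generates
soil-like spectra with known ground truth (`generate_spectra()`). The
generative model is Beer–Lambert-like: absorbance is assembled as a
smooth continuum plus Gaussian absorption features plus noise, and
reflectance is `10^(-absorbance)`, clipped into (0, 1] with a guard that
refuses configurations clipping more than 5% of values.

TN acts through a normalised saturating link `g = 1 - exp(-TN/tau)`
(tau = 5 mg·kg⁻¹, TN uniform on 7–19 mg·kg⁻¹ with small site shifts), a
continuum darkening term, and the feature depths. Design choices that
matter, with their reasons:

* **Absorbance-domain assembly.** If reflectance were assembled
  multiplicatively, log(1/R) would carry band-diverse curvature in g and
  a many-band linear model could reconstruct higher powers of g,
  linearising the saturating link almost perfectly — the nonlinear
  regressor would then have nothing to add. With absorbance affine in g,
  all TN information flows through one nonlinear scalar, which is the
  regime the method presumes: linear readouts cap at the TN-vs-g
  correlation (~0.92 R² at these settings), the ANFIS can exceed it.
* **Two feature families.** Narrow visible chromophore features (480,
  560, 680, 740 nm; widths 3–4 nm) carry the strongest TN coupling; a
  comb of minor overtone features and the broad water/clay bands (1400,
  1905, 2200 nm) spans the rest of the grid.
* **Interference, not just noise.** A shared organic-matter/moisture
  factor perturbs the link read by every feature beyond 800 nm: one
  common factor cannot be averaged away across bands, so the SWIR region
  alone supports only a capped validation R². Medium-width random-depth
  absorptions sit exactly on the narrow visible features: a smoothed
  narrow feature leaves a residue with the same shape as these
  confounders, so deep fixed-level smoothing genuinely destroys the
  visible TN signal instead of merely displacing it. Coarse baseline
  wander (approximation-space noise beyond the deepest smoothing scale)
  removes the remaining leak. Without these ingredients, wavelet
  smoothing — a linear projection — loses almost no information that a
  linear pooling regression cannot recover from neighbouring bands, and
  no denoising strategy can look better than any other.
* **Band-localised burr noise.** White noise restricted to wavelet
  detail scales 1..5 (via the same transform) and shaped by an amplitude
  profile rising toward the SWIR, plus a small white floor. The noise
  scale is recorded in the ground truth, so level-map recovery is
  scored against a known answer.

The ground-truth record stores clean spectra, the noise realisation, the
link values, the interference factor, and the designated signal bands.

What the synthetic tests show: every pipeline stage behaves per its
contract, learned state never touches validation samples, and under the
stated generative assumptions the reference performance ordering
(LCMCS ≥ CS, LCMCS ≥ LCM ≥ PLS on seed-averaged validation R²)
reproduces with comfortable margins. What they do not show: that those
generative assumptions hold for any particular real soil archive —
feature positions, interference strength and noise profiles are
stylised, spectra lack instrument artefacts (splice steps, water-vapour
residuals), and TN co-variation with other constituents is reduced to a
single factor. Performance on real spectra must be established on real
spectra.

## Degenerate inputs and numerical edges

Zero-variance bands are flagged incomputable and excluded from selection
rather than propagating NaN; an all-incomputable band is excluded from
the OSP. An empty band selection aborts a pipeline run with the maximum
observed |r|. TN values must be strictly positive (relative error
divides by them). Reflectance must lie in (0, 1] before the log
transform; violations are reported with sample and wavelength. All
randomness (splits, generator, jittered initialisations) flows from a
single integer seed, and repeated runs produce byte-identical persisted
reports.

## Problem sizes used in the checks

The packaged checks run the full 280 × 2151 generator and all four
pipelines across ten seeds, plus smaller property tests (tens of samples,
64–512 bands), chosen to exercise every code path at full spectral
resolution while keeping a complete run in the order of a few minutes on
one CPU.
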
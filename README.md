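# lcmcs

Chemometric calibration of soil total nitrogen (TN, mg·kg⁻¹) from
visible/near-infrared reflectance spectra (350–2500 nm), built around the
**local correlation maximization – complementary superiority** (LCMCS)
method and its three comparison pipelines (PLS, LCM, CS).

Field soil spectra carry fine-scale "burr" noise on top of broad
absorption structure, and the TN→spectrum relation is nonlinear. The
LCMCS pipeline addresses both at once:

1. **Spectral transforms** — original reflectance R, first derivative
   (FDR), reciprocal logarithm log(1/R), and the first derivative of the
   reciprocal logarithm (log[1/R])′.
2. **Local correlation maximization (LCM)** — every spectrum is
   decomposed with a 5-level sym8 wavelet transform; reconstructing with
   the detail scales 1..k zeroed gives progressively smoother versions.
   For each band the level (0 = untouched) whose values correlate most
   strongly with TN across the calibration samples is retained. The
   winning correlations form the *optimal correlative curve* (OCC); the
   winning band values, assembled band-wise, form the *optimal spectrum*
   (OSP). Smoothing depth is thus chosen locally: noisy regions get deep
   smoothing, fine diagnostic detail is preserved where it matters.
3. **Band selection** — bands whose |r| with TN exceeds a threshold
   (p < 0.01 significance via the exact t-inversion, or a fixed cutoff
   such as |r| > 0.40).
4. **PLS** — NIPALS partial least squares compresses the selected
   (collinear) bands to a few orthogonal latent variables:
   Y = UQ + F, X = TP + E, with inner relation U = TB + E_d.
5. **ANFIS (complementary superiority)** — a first-order Takagi–Sugeno
   adaptive neuro-fuzzy inference system on five PLS latent scores:
   generalized bell memberships μ(x) = 1/(1 + ((x−c)/a)^(2b)), product
   rule firing, normalisation (Σŵ = 1), linear consequents, hybrid
   least-squares + gradient-descent training. It captures the saturating
   nonlinearity a purely linear PLS readout cannot.

The four reference pipelines are available as presets: `pls`
(fixed level-5 smoothing + PLS), `lcm` (OSP + PLS), `cs` (fixed level-4 +
PLS scores + ANFIS), `lcmcs` (OSP + PLS scores + ANFIS). Models are
calibrated on 150 samples and validated on 130 (sites 55/50/45 and
45/45/40), and reported with R², RMSE (mg·kg⁻¹) and mean relative error
(%) per split and per site.

Because the original field data are not publicly deposited, the package
ships a first-class synthetic generator (`generate_spectra()`) that
emulates soil-like spectra: a Beer–Lambert absorbance continuum, narrow
visible chromophore features and broad SWIR water/overtone features
coupled to TN through a saturating link, organic-matter/moisture
interference, and band-localised wavelet-domain burr noise — so every
stage, and the four-model comparison itself, is testable end to end.

## Worked example

```r
library(lcmcs)

gen <- generate_spectra(synthetic_config(), seed = 7)
gen$spectra
#> <spectra> 280 samples x 2151 bands [350-2500 nm], transform = REF, sites: C:100 F:85 R:95

fit <- run_method(gen$spectra, gen$targets, preset_config("lcmcs"), seed = 7)
fit$occ
#> <occ_result> 2151 bands, levels 0..5; max |r| = 0.93 at 557 nm
fit$report
#> <evaluation_report> method=LCMCS, transform=FDR_LOG_INV, denoise=lcm_osp, level=NA, selection=p<0.01, n_bands=1776, lvs=5, seed=7
#> # A tibble: 8 x 6
#>   split       site        n    r2  rmse   mre
#> 1 calibration overall   150 0.997 0.173 0.934
#> 2 calibration C          55 0.998 0.126 0.851
#> 3 calibration R          50 0.997 0.174 0.926
#> 4 calibration F          45 0.994 0.217 1.05
#> 5 validation  overall   130 0.913 0.901 4.26
#> 6 validation  C          45 0.946 0.669 4.29
#> 7 validation  R          45 0.862 1.24  4.93
#> 8 validation  F          40 0.945 0.641 3.49
```

Validation R² = 0.913 with RMSE 0.90 mg·kg⁻¹ means the frozen pipeline
(level map, band mask, PLS projector and ANFIS all learned on the 150
calibration samples only) explains 91% of the TN variance among the 130
held-out samples, with a typical error under 1 mg·kg⁻¹ (≈4% relative).
The OCC found its strongest TN response (|r| = 0.93) at 557 nm, inside
the narrow visible chromophore feature the generator plants.

Comparing all four pipelines on the same split:

```r
compare_methods(gen$spectra, gen$targets, seed = 7)
#>   method n_bands lvs r2_cal rmse_cal r2_val rmse_val mre_val
#> 1  LCMCS    1776   5  0.997    0.173  0.913    0.901    4.26
#> 2    LCM    1776   8  0.946    0.729  0.879    1.059    6.59
#> 3     CS     921   5  0.935    0.802  0.732    1.580    8.96
#> 4    PLS    1539   8  0.807    1.379  0.626    1.866   10.95
```

Adaptive per-band denoising (LCM rows) beats fixed-level smoothing, the
ANFIS regressor beats the linear readout, and their combination (LCMCS)
is best on both counts.

`autoplot()` methods exist for spectra, OCC results and fitted pipelines;
`tidy()`/`glance()` for the PLS and ANFIS models. A thin command-line
front end lives at `inst/scripts/lcmcs` (`synth`, `run`, `compare`
subcommands over CSV/YAML files).

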
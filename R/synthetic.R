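#' Configuration for the synthetic soil-spectra generator
#'
#' Defaults emulate the field conditions the pipeline is designed for:
#' 280 samples from three sites (100/95/85), TN between 7 and 19 mg/kg
#' with site-level shifts, and a smooth soil reflectance continuum on the
#' 350-2500 nm grid at 1 nm. TN expresses itself twice: broad water/clay
#' absorption features at 1400, 1905 and 2200 nm sit in the noisy SWIR,
#' and narrow organic-matter chromophore features (480-740 nm) sit in the
#' quiet visible region; all depths deepen with TN through a saturating
#' link, so reflectance decreases with TN and the TN-to-spectrum relation
#' is nonlinear. High-frequency "burr" noise is synthesised in the wavelet
#' detail domain at scales 1..`noise_scale` with an amplitude profile that
#' grows toward the SWIR. Deep fixed-level smoothing therefore cleans the
#' broad features but flattens the narrow ones, while leaving spectra raw
#' keeps the narrow features but drowns the broad ones — the per-band
#' level trade-off the LCM stage exists to resolve.
#'
#' @param n_samples Total samples.
#' @param sites Named per-site sample counts.
#' @param tn_range TN range in mg/kg.
#' @param site_tn_shift Named additive TN shift per site (mg/kg).
#' @param wavelengths Band grid (nm).
#' @param feature_centers,feature_widths Absorption feature centres and
#'   Gaussian widths (nm).
#' @param feature_depths Base absorbance depth of each feature.
#' @param feature_coupling Additional depth per unit of the (normalised)
#'   TN link.
#' @param confounder_centers,confounder_widths TN-independent absorptions
#'   with random per-sample depths: medium-width bands co-located with the
#'   narrow visible TN features (once a narrow feature is smoothed away
#'   its residue has the same shape as these, so over-smoothing makes the
#'   visible TN signal unrecoverable), broad iron-oxide-like bands in the
#'   visible, and moisture-like bands on the 1400/1905 nm water features.
#' @param swir_interference Strength (as a fraction of the link's spread)
#'   of a shared organic-matter/moisture factor perturbing the link that
#'   drives every feature beyond 800 nm; the visible chromophore features
#'   read the pure TN link. This caps how much TN information the
#'   SWIR/overtone region can ever deliver, as one common factor cannot
#'   be averaged away across bands.
#' @param confounder_depth,confounder_sd Mean and spread of the random
#'   confounder depths.
#' @param darkening Absorbance added at the top of the TN link (overall
#'   reflectance darkening with increasing TN).
#' @param tn_tau Scale (mg/kg) of the saturating exponential link
#'   `1 - exp(-TN/tn_tau)`.
#' @param nonlinearity Mix between a linear TN link (0) and the saturating
#'   link (1).
#' @param site_offsets Named additive absorbance offset per site.
#' @param smooth_nuisance Amplitude of a per-sample smooth (cubic) random
#'   absorbance perturbation (a TN-independent continuum confounder).
#' @param baseline_wander Standard deviation of coarse-scale random
#'   baseline structure (absorbance units): smooth noise with correlation
#'   length beyond the deepest smoothing scale, present at every band. It
#'   survives wavelet smoothing at any level, so information carried only
#'   in fine scales is genuinely destroyed, not merely displaced, by
#'   over-smoothing.
#' @param burr_amplitude Base amplitude of the fine-scale noise.
#' @param burr_slope Relative amplitude increase across the grid.
#' @param noise_scale Wavelet detail scales 1..k carrying the burr noise.
#' @param white_noise Additive white noise floor (sd).
#' @param wavelet Wavelet used to band-limit the burr noise.
#' @return A list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(
    n_samples = 280L,
    sites = c(C = 100L, R = 95L, F = 85L),
    tn_range = c(7, 19),
    site_tn_shift = c(C = -1.5, R = 0, F = 1.5),
    wavelengths = 350:2500,
    feature_centers = c(480, 560, 680, 740, 825, 910, 1020, 1150, 1250,
                        1330, 1400, 1550, 1650, 1750, 1905, 2040, 2120,
                        2200, 2290, 2380, 2450),
    feature_widths = c(3, 3, 4, 4, 8, 12, 10, 15, 12, 8, 28,
                       10, 20, 14, 45, 12, 18, 32, 10, 16, 12),
    feature_depths = c(0.03, 0.04, 0.05, 0.03, 0.03, 0.03, 0.04, 0.03, 0.04,
                       0.03, 0.10, 0.03, 0.04, 0.03, 0.16, 0.03, 0.04, 0.08,
                       0.03, 0.04, 0.03),
    feature_coupling = c(0.12, 0.18, 0.18, 0.12, 0.03, 0.03, 0.03, 0.03,
                         0.03, 0.03, 0.05, 0.03, 0.04, 0.03, 0.06, 0.03,
                         0.04, 0.04, 0.04, 0.04, 0.03),
    confounder_centers = c(480, 560, 680, 740, 600, 690, 1420, 1930),
    confounder_widths = c(8, 8, 10, 10, 45, 55, 60, 70),
    confounder_depth = 0.06,
    confounder_sd = 0.05,
    swir_interference = 0.5,
    darkening = 0.25,
    tn_tau = 5,
    nonlinearity = 1,
    site_offsets = c(C = 0, R = 0.015, F = -0.015),
    smooth_nuisance = 0.005,
    baseline_wander = 0.01,
    burr_amplitude = 0.0002,
    burr_slope = 12,
    noise_scale = 5L,
    white_noise = 2e-4,
    wavelet = "sym8") {
  if (sum(sites) != n_samples) stop("site counts must sum to n_samples")
  if (any(tn_range <= 0)) stop("tn_range must be positive")
  if (burr_amplitude < 0 || white_noise < 0) stop("noise amplitudes must be >= 0")
  structure(as.list(environment()), class = "synthetic_config")
}

# normalised TN link in [0,1] over tn_range: mix of linear and saturating
tn_link <- function(tn, cfg) {
  lo <- cfg$tn_range[1]; hi <- cfg$tn_range[2]
  lin <- (tn - lo) / (hi - lo)
  sat_raw <- 1 - exp(-tn / cfg$tn_tau)
  sat <- (sat_raw - (1 - exp(-lo / cfg$tn_tau))) /
    ((1 - exp(-hi / cfg$tn_tau)) - (1 - exp(-lo / cfg$tn_tau)))
  (1 - cfg$nonlinearity) * lin + cfg$nonlinearity * sat
}

#' Generate a synthetic soil spectra dataset
#'
#' See [synthetic_config()] for the generative model. The returned ground
#' truth records the clean (noise-free) spectra, the noise realisation,
#' the TN link values, the designated signal bands (within one Gaussian
#' width of a feature centre) and the injected noise scale, so denoising
#' stages can be scored against a known answer.
#'
#' @param cfg A `"synthetic_config"`.
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#' @return A list with `spectra` (a [spectra], transform `"REF"`),
#'   `targets` (tibble `sample_id`, `site`, `tn`), and `truth` (list).
#' @export
generate_spectra <- function(cfg = synthetic_config(), seed = 1L) {
  set.seed(seed)
  wl <- as.numeric(cfg$wavelengths)
  nb <- length(wl)
  n <- cfg$n_samples
  site <- rep(names(cfg$sites), times = cfg$sites)
  ids <- paste0("s", seq_len(n))
  shift <- cfg$site_tn_shift[site]
  lo <- pmax(cfg$tn_range[1], cfg$tn_range[1] + shift)
  hi <- pmin(cfg$tn_range[2], cfg$tn_range[2] + shift)
  tn <- stats::runif(n, lo, hi)
  g <- tn_link(tn, cfg)
  # shared organic-matter/moisture factor perturbing the link read by the
  # overtone (>800 nm) features
  m <- stats::rnorm(n)
  g_swir <- g + cfg$swir_interference * stats::sd(g) * m

  # Beer-Lambert-style synthesis: the spectrum is assembled in the
  # absorbance domain, affine in the TN link g, then exponentiated, so
  # log10(1/R) is an affine function of g plus confounders and noise
  continuum_a <- 0.9 - 0.55 / (1 + exp(-(wl - 800) / 350))
  absorb <- matrix(0, n, nb)
  signal <- rep(FALSE, nb)   # broad features: smoothing is the right answer
  fine <- rep(FALSE, nb)     # narrow features: detail must be preserved
  for (k in seq_along(cfg$feature_centers)) {
    shape <- exp(-(wl - cfg$feature_centers[k])^2 /
                   (2 * cfg$feature_widths[k]^2))
    g_k <- if (cfg$feature_centers[k] < 800) g else g_swir
    depth <- cfg$feature_depths[k] + cfg$feature_coupling[k] * g_k
    absorb <- absorb + outer(depth, shape)
    near <- abs(wl - cfg$feature_centers[k]) <= cfg$feature_widths[k]
    if (cfg$feature_widths[k] > 20) signal <- signal | near else fine <- fine | near
  }
  # broad TN-independent absorptions with random per-sample depth
  conf_depths <- matrix(0, n, length(cfg$confounder_centers))
  for (k in seq_along(cfg$confounder_centers)) {
    shape <- exp(-(wl - cfg$confounder_centers[k])^2 /
                   (2 * cfg$confounder_widths[k]^2))
    conf_depths[, k] <- pmax(
      stats::rnorm(n, cfg$confounder_depth, cfg$confounder_sd), 0)
    absorb <- absorb + outer(conf_depths[, k], shape)
  }
  # per-sample smooth nuisance: random cubic in scaled wavelength
  z <- (wl - mean(wl)) / (diff(range(wl)) / 2)
  coefs <- matrix(stats::rnorm(n * 4, 0, cfg$smooth_nuisance), n, 4)
  nuis <- coefs %*% rbind(rep(1, nb), z, z^2, z^3)
  # coarse-scale baseline wander: approximation-space noise (scales beyond
  # 2^6 bands), built by stripping all detail from white noise
  if (cfg$baseline_wander > 0) {
    lev6 <- min(6L, max_dwt_level(nb, cfg$wavelet))
    wdec <- row_wavedec(matrix(stats::rnorm(n * nb), n, nb), lev6,
                        cfg$wavelet)
    for (k in seq_len(lev6)) wdec$details[[k]][] <- 0
    gp <- row_waverec(wdec)
    nuis <- nuis + gp * (cfg$baseline_wander / stats::sd(gp))
  }
  absorbance <- outer(rep(1, n), continuum_a) + cfg$site_offsets[site] +
    nuis + cfg$darkening * g + absorb
  clean <- 10^(-absorbance)

  # band-limited burr noise: white noise restricted to detail scales
  # 1..noise_scale, then shaped by the amplitude profile
  amp <- cfg$burr_amplitude * (1 + cfg$burr_slope * (wl - wl[1]) /
                                 (wl[nb] - wl[1]))
  noise <- matrix(0, n, nb)
  if (cfg$burr_amplitude > 0) {
    white <- matrix(stats::rnorm(n * nb), n, nb)
    dec <- row_wavedec(white, cfg$noise_scale, cfg$wavelet)
    dec$approx[] <- 0
    band_limited <- row_waverec(dec)
    noise <- sweep(band_limited, 2, amp, `*`)
  }
  if (cfg$white_noise > 0) {
    noise <- noise + matrix(stats::rnorm(n * nb, 0, cfg$white_noise), n, nb)
  }
  vals <- clean + noise
  n_clip <- sum(vals <= 0 | vals > 1)
  if (n_clip > 0.05 * length(vals)) {
    stop("parameters drive ", round(100 * n_clip / length(vals), 1),
         "% of reflectance outside (0,1]; rescale the configuration")
  }
  vals <- pmin(pmax(vals, 1e-6), 1)
  s <- spectra(vals, wl, sample_ids = ids, site = site, transform = "REF")
  list(
    spectra = s,
    targets = tibble::tibble(sample_id = ids, site = site, tn = tn),
    truth = list(
      clean = clean, noise = noise, link = g, signal_bands = which(signal),
      fine_bands = which(fine), confounder_depths = conf_depths,
      swir_factor = m,
      noise_scale = cfg$noise_scale, seed = seed, config = cfg
    )
  )
}

#' Write a ready-made synthetic fixture to disk
#'
#' `kind = "tiny"` writes a 12-sample, 64-band set for fast unit tests
#' (features compressed into the short grid); `kind = "field_shaped"`
#' writes the full default configuration (280 samples x 2151 bands, three
#' sites 100/95/85). Files: `spectra.csv` (wide), `targets.csv`, and
#' `truth.json` (link parameters, signal bands, noise scale, seed).
#'
#' @param kind `"tiny"` or `"field_shaped"`.
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @return Invisibly, the paths written.
#' @export
make_fixture <- function(kind = c("tiny", "field_shaped"), dir, seed = 1L) {
  kind <- match.arg(kind)
  cfg <- if (kind == "tiny") tiny_config() else synthetic_config()
  gen <- generate_spectra(cfg, seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "spectra.csv")
  p2 <- file.path(dir, "targets.csv")
  p3 <- file.path(dir, "truth.json")
  write_spectra(gen$spectra, p1, "wide")
  write_targets(gen$targets, p2)
  jsonlite::write_json(
    list(
      kind = kind, seed = seed, link = gen$truth$link,
      signal_bands = gen$truth$signal_bands,
      noise_scale = gen$truth$noise_scale
    ),
    p3, digits = NA, auto_unbox = TRUE
  )
  invisible(c(spectra = p1, targets = p2, truth = p3))
}

#' @rdname make_fixture
#' @export
tiny_config <- function() {
  synthetic_config(
    n_samples = 12L,
    sites = c(C = 5L, R = 4L, F = 3L),
    wavelengths = 350:413,
    feature_centers = c(370, 390, 405),
    feature_widths = c(4, 6, 5),
    noise_scale = 1L,
    burr_amplitude = 0.004
  )
}
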
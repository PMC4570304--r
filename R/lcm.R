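#' Multilevel smoothed stack of a spectra set
#'
#' Decomposes every spectrum with a multilevel discrete wavelet transform
#' and reconstructs it at each depth with the detail coefficients at scales
#' 1..k zeroed, giving progressively smoother versions of the input. Level
#' 0 is the untouched input; levels 1..`max_level` remove successively
#' coarser high-frequency structure ("burrs") while keeping band alignment.
#'
#' @param x A [spectra] object.
#' @param wavelet Wavelet name (default `"sym8"`, see [wavelet_filters()]).
#' @param max_level Decomposition depth (default 5).
#' @return An object of class `"decomposed_stack"`: a list with `base`
#'   (level 0) and `levels` (list of [spectra], level 1..`max_level`),
#'   plus `wavelet` and `max_level`.
#' @export
decompose_stack <- function(x, wavelet = "sym8", max_level = 5L) {
  stopifnot(is_spectra(x), max_level >= 1L)
  sm <- row_smooth_levels(unclass(x), max_level, wavelet)
  structure(
    list(
      base = x,
      levels = lapply(sm, restamp, template = x),
      wavelet = wavelet,
      max_level = as.integer(max_level)
    ),
    class = "decomposed_stack"
  )
}

#' @export
print.decomposed_stack <- function(x, ...) {
  cat("<decomposed_stack> levels 0..", x$max_level, " (", x$wavelet, "), ",
      nrow(x$base), " samples x ", ncol(x$base), " bands\n", sep = "")
  invisible(x)
}

stack_level <- function(stack, k) {
  if (k == 0) stack$base else stack$levels[[k]]
}

#' Per-band correlations between a decomposed stack and the target
#'
#' For every decomposition level 0..L and every band, the Pearson
#' correlation across samples between the (smoothed) band values and the
#' target property. Bands whose values have zero variance at a level are
#' flagged `computable = FALSE` rather than propagating NaN.
#'
#' @param stack A `"decomposed_stack"` from [decompose_stack()].
#' @param targets Target table (`sample_id`, `tn`) or a numeric vector
#'   already aligned to the stack's sample order.
#' @return A tibble with columns `level`, `wavelength`, `r`, `computable`,
#'   and attribute `n` (sample count).
#' @export
band_correlations <- function(stack, targets) {
  y <- if (is.numeric(targets)) targets else align_targets(stack$base, targets)
  n <- nrow(stack$base)
  if (n < 3) stop("need at least 3 samples for band correlations")
  if (length(y) != n) stop("target length != sample count")
  wl <- wavelengths(stack$base)
  prof <- purrr::map_dfr(0:stack$max_level, function(k) {
    v <- unclass(stack_level(stack, k))
    r <- suppressWarnings(as.vector(stats::cor(v, y)))
    sdx <- matrixStats_colSds(v)
    comp <- sdx > 0 & stats::sd(y) > 0
    r[!comp] <- NA_real_
    tibble::tibble(level = k, wavelength = wl, r = r, computable = comp)
  })
  attr(prof, "n") <- n
  prof
}

# column standard deviations without an extra dependency
matrixStats_colSds <- function(m) {
  n <- nrow(m)
  mu <- colMeans(m)
  sqrt(pmax(colSums(m^2) / n - mu^2, 0) * n / (n - 1))
}

#' Optimal correlative curve and optimal spectrum
#'
#' For each band, picks the decomposition level (0 = untouched input)
#' whose band values correlate most strongly in absolute value with the
#' target; ties break toward the lowest level, preserving detail. The
#' winning signed correlations form the optimal correlative curve (OCC)
#' and the winning band values, assembled band-wise across levels, the
#' optimal spectrum (OSP).
#'
#' @param stack A `"decomposed_stack"`.
#' @param profiles Output of [band_correlations()] on that stack. If
#'   omitted, computed from `targets`.
#' @param targets Target table or aligned numeric vector (used only when
#'   `profiles` is missing).
#' @return An object of class `"occ_result"`: list with `occ` (tibble:
#'   `wavelength`, `level`, `r`, `excluded`), `level_map` (integer per
#'   band), `osp` (a [spectra]), `wavelet`, `max_level`, `n`.
#' @export
build_occ <- function(stack, profiles = NULL, targets = NULL) {
  if (is.null(profiles)) {
    if (is.null(targets)) stop("supply profiles or targets")
    profiles <- band_correlations(stack, targets)
  }
  wl <- wavelengths(stack$base)
  L <- stack$max_level
  wide <- matrix(NA_real_, length(wl), L + 1L)
  for (k in 0:L) {
    pk <- profiles[profiles$level == k, ]
    if (nrow(pk) != length(wl) || !isTRUE(all.equal(pk$wavelength, wl))) {
      stop("profiles do not cover levels 0..L on the stack's band grid")
    }
    wide[, k + 1L] <- pk$r
  }
  a <- abs(wide)
  excluded <- apply(a, 1, function(z) all(is.na(z)))
  level_map <- integer(length(wl))
  occ_r <- rep(NA_real_, length(wl))
  ok <- !excluded
  # ties break toward the lowest level: max.col(ties.method="first") on
  # columns ordered 0..L does exactly that once NAs are floored out
  a_f <- a
  a_f[is.na(a_f)] <- -Inf
  win <- max.col(a_f, ties.method = "first") - 1L
  level_map[ok] <- win[ok]
  occ_r[ok] <- wide[cbind(which(ok), win[ok] + 1L)]
  osp_vals <- unclass(stack$base)
  for (k in seq_len(L)) {
    sel <- ok & level_map == k
    if (any(sel)) osp_vals[, sel] <- unclass(stack$levels[[k]])[, sel]
  }
  structure(
    list(
      occ = tibble::tibble(
        wavelength = wl, level = level_map, r = occ_r, excluded = excluded
      ),
      level_map = level_map,
      osp = restamp(stack$base, osp_vals),
      wavelet = stack$wavelet,
      max_level = L,
      n = attr(profiles, "n")
    ),
    class = "occ_result"
  )
}

#' @export
print.occ_result <- function(x, ...) {
  r <- x$occ$r[!x$occ$excluded]
  i <- which.max(abs(r))
  cat("<occ_result> ", nrow(x$occ), " bands, levels 0..", x$max_level,
      "; max |r| = ", round(max(abs(r)), 3), " at ",
      x$occ$wavelength[!x$occ$excluded][i], " nm\n", sep = "")
  invisible(x)
}

#' Apply a learned level map to new spectra
#'
#' Decomposes new spectra with the same wavelet and depth used to learn a
#' level map and assembles the per-band smoothed values the map dictates.
#' Applying the calibration set's own map reproduces its stored OSP, and
#' validation spectra are denoised without ever touching the learned state.
#'
#' @param x A [spectra] object on the same wavelength grid as the map.
#' @param level_map Integer vector (one level in 0..`max_level` per band),
#'   or an `"occ_result"` whose `level_map` is used.
#' @param wavelet,max_level Decomposition settings (defaults taken from an
#'   `"occ_result"` if one is supplied).
#' @return A [spectra] object with the map applied.
#' @export
apply_level_map <- function(x, level_map, wavelet = "sym8", max_level = 5L) {
  if (inherits(level_map, "occ_result")) {
    occ <- level_map
    if (!isTRUE(all.equal(occ$occ$wavelength, wavelengths(x)))) {
      stop("wavelength grid does not match the level map's grid")
    }
    level_map <- occ$level_map
    wavelet <- occ$wavelet
    max_level <- occ$max_level
  }
  if (length(level_map) != ncol(x)) {
    stop("level_map length != band count")
  }
  if (all(level_map == 0L)) return(x)
  stack <- decompose_stack(x, wavelet, max_level)
  vals <- unclass(stack$base)
  for (k in seq_len(max_level)) {
    sel <- level_map == k
    if (any(sel)) vals[, sel] <- unclass(stack$levels[[k]])[, sel]
  }
  restamp(x, vals)
}
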
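#' Reciprocal-logarithm transform, log10(1/R)
#'
#' The absorbance-like transform used alongside the first derivative:
#' each reflectance value R in (0,1] becomes log10(1/R).
#'
#' @param x A [spectra] object with `transform_tag(x) == "REF"`.
#' @return A [spectra] object tagged `"LOG_INV"` on the same grid.
#' @export
reciprocal_log <- function(x) {
  stopifnot(is_spectra(x))
  if (transform_tag(x) != "REF") {
    stop("reciprocal_log expects original reflectance (REF) input")
  }
  v <- unclass(x)
  if (any(v <= 0)) {
    bad <- which(v <= 0, arr.ind = TRUE)[1, ]
    stop(
      "non-positive reflectance at sample ", sample_ids(x)[bad[1]],
      ", band ", wavelengths(x)[bad[2]], " nm"
    )
  }
  restamp(x, log10(1 / v), transform = "LOG_INV")
}

#' First-derivative transform (per nm)
#'
#' Central differences at interior bands, one-sided differences at the two
#' edge bands, so the output stays on the input band grid. Exact for
#' spectra affine in wavelength.
#'
#' @param x A [spectra] object (any transform tag).
#' @return A [spectra] object tagged `"FDR"` (from `"REF"`) or
#'   `"FDR_LOG_INV"` (from `"LOG_INV"`).
#' @export
first_derivative <- function(x) {
  stopifnot(is_spectra(x))
  n <- ncol(x)
  if (n < 3) stop("first derivative needs at least 3 bands")
  wl <- wavelengths(x)
  v <- unclass(x)
  d <- matrix(0, nrow(v), n)
  d[, 2:(n - 1)] <- (v[, 3:n] - v[, 1:(n - 2)]) / (wl[3:n] - wl[1:(n - 2)])
  d[, 1] <- (v[, 2] - v[, 1]) / (wl[2] - wl[1])
  d[, n] <- (v[, n] - v[, n - 1]) / (wl[n] - wl[n - 1])
  tag <- switch(transform_tag(x),
    REF = "FDR",
    LOG_INV = "FDR_LOG_INV",
    stop("first_derivative applies to REF or LOG_INV spectra")
  )
  restamp(x, d, transform = tag)
}

#' Apply a named spectral transform
#'
#' Dispatcher over the four transform kinds: original reflectance (`REF`),
#' first derivative (`FDR`), reciprocal logarithm (`LOG_INV`), and first
#' derivative of the reciprocal logarithm (`FDR_LOG_INV`, the composition
#' `first_derivative(reciprocal_log(x))`).
#'
#' @param x A [spectra] object tagged `"REF"`.
#' @param kind One of `"REF"`, `"FDR"`, `"LOG_INV"`, `"FDR_LOG_INV"`.
#' @return A [spectra] object tagged `kind`.
#' @export
transform_spectra <- function(x, kind = c("REF", "FDR", "LOG_INV",
                                          "FDR_LOG_INV")) {
  kind <- match.arg(kind)
  switch(kind,
    REF = x,
    FDR = first_derivative(x),
    LOG_INV = reciprocal_log(x),
    FDR_LOG_INV = first_derivative(reciprocal_log(x))
  )
}
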
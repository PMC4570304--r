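#' Discrete wavelet filter banks
#'
#' Returns the analysis/synthesis filter bank for the wavelets the package
#' supports. `sym8` (Symlet of order 8, 16 taps) is the default basis used
#' throughout the denoising pipeline; `haar` is provided mainly because its
#' two-tap filters make hand-checkable test cases.
#'
#' @param wavelet Wavelet name, `"sym8"` or `"haar"`.
#' @return A list with components `dec_lo`, `dec_hi`, `rec_lo`, `rec_hi`
#'   (numeric filter taps) and `length` (the common tap count).
#' @export
wavelet_filters <- function(wavelet = "sym8") {
  wavelet <- match.arg(wavelet, c("sym8", "haar"))
  if (wavelet == "sym8") {
    dec_lo <- c(
      -0.0033824159510061256, -0.0005421323317911481, 0.03169508781149298,
      0.007607487324917605, -0.1432942383508097, -0.061273359067658524,
      0.4813596512583722, 0.7771857517005235, 0.3644418948353314,
      -0.05194583810770904, -0.027219029917056003, 0.049137179673607506,
      0.003808752013890615, -0.01495225833704823, -0.0003029205147213668,
      0.0018899503327594609
    )
  } else {
    s <- 1 / sqrt(2)
    dec_lo <- c(s, s)
  }
  n <- length(dec_lo)
  # quadrature mirror relations for an orthogonal bank
  dec_hi <- rev(dec_lo) * (-1)^(seq_len(n))
  rec_lo <- rev(dec_lo)
  rec_hi <- dec_lo * (-1)^(seq_len(n) - 1L)
  list(
    name = wavelet, dec_lo = dec_lo, dec_hi = dec_hi,
    rec_lo = rec_lo, rec_hi = rec_hi, length = n
  )
}

#' Maximum useful decomposition depth
#'
#' The deepest level at which the data, rather than the boundary
#' extension, still dominates every coefficient:
#' `floor(log2(n_bands / (filter_length - 1)))`.
#'
#' @param n_bands Number of spectral bands.
#' @param wavelet Wavelet name (see [wavelet_filters()]).
#' @return Integer maximum level (possibly 0).
#' @export
max_dwt_level <- function(n_bands, wavelet = "sym8") {
  lf <- wavelet_filters(wavelet)$length
  if (n_bands < lf - 1L) return(0L)
  as.integer(floor(log2(n_bands / (lf - 1L))))
}

# symmetric (half-point) extension indices for a signal of length n,
# padded by `pad` samples on each side; requires n >= pad
sym_ext_idx <- function(n, pad) {
  if (n < pad) {
    stop("signal length ", n, " too short for symmetric extension of ", pad)
  }
  c(rev(seq_len(pad)), seq_len(n), n + 1L - seq_len(pad))
}

# One analysis step along the rows' columns: X is samples x n.  Returns
# list(cA, cD), each samples x floor((n + lf - 1) / 2).  Symmetric
# half-point boundary extension; indexing matches the usual convolve-and
# -downsample convention so round trips are exact.
dwt_step <- function(X, filt) {
  n <- ncol(X)
  lf <- filt$length
  ext <- X[, sym_ext_idx(n, lf - 1L), drop = FALSE]
  o <- (n + lf - 1L) %/% 2L
  ks <- 2L * (seq_len(o) - 1L)
  cA <- matrix(0, nrow(X), o)
  cD <- matrix(0, nrow(X), o)
  for (j in seq_len(lf)) {
    cols <- 18L - j - 16L + lf + ks   # = (lf + 2 - j) + ks
    sub <- ext[, cols, drop = FALSE]
    cA <- cA + filt$dec_lo[j] * sub
    cD <- cD + filt$dec_hi[j] * sub
  }
  list(cA = cA, cD = cD)
}

# One synthesis step: cA, cD are samples x o; returns samples x target_len
# (target_len must be 2*o - lf + 2 or one less, the length before analysis).
idwt_step <- function(cA, cD, filt, target_len) {
  o <- ncol(cA)
  lf <- filt$length
  full_len <- 2L * o + lf - 1L
  y <- matrix(0, nrow(cA), full_len)
  idx0 <- 2L * (seq_len(o) - 1L)     # upsampled coefficient positions - 1
  for (j in seq_len(lf)) {
    cols <- idx0 + j
    y[, cols] <- y[, cols] + filt$rec_lo[j] * cA + filt$rec_hi[j] * cD
  }
  rec_len <- 2L * o - lf + 2L
  if (target_len > rec_len || target_len < rec_len - 1L) {
    stop("inconsistent coefficient/target lengths in idwt")
  }
  y[, (lf - 2L) + seq_len(target_len), drop = FALSE]
}

#' Multilevel wavelet decomposition of spectra rows
#'
#' Decomposes every row of a samples-by-bands matrix to `level` scales.
#'
#' @param X Numeric matrix, samples in rows.
#' @param level Decomposition depth (>= 1).
#' @param wavelet Wavelet name.
#' @return A list of class `"wavedec"` with `approx` (deepest approximation
#'   matrix), `details` (list of detail matrices, level 1 = finest),
#'   `lengths` (signal length entering each analysis step), `wavelet`,
#'   `level`.
#' @export
row_wavedec <- function(X, level, wavelet = "sym8") {
  filt <- wavelet_filters(wavelet)
  n <- ncol(X)
  maxlev <- max_dwt_level(n, wavelet)
  if (level < 1L) stop("level must be >= 1")
  if (level > maxlev) {
    stop(
      "decomposition level ", level, " exceeds the maximum feasible level ",
      maxlev, " for ", n, " bands with ", wavelet
    )
  }
  details <- vector("list", level)
  lengths <- integer(level)
  cur <- X
  for (k in seq_len(level)) {
    lengths[k] <- ncol(cur)
    step <- dwt_step(cur, filt)
    details[[k]] <- step$cD
    cur <- step$cA
  }
  structure(
    list(
      approx = cur, details = details, lengths = lengths,
      wavelet = wavelet, level = level
    ),
    class = "wavedec"
  )
}

#' Multilevel reconstruction
#'
#' Inverts [row_wavedec()]. Detail matrices may be zeroed by the caller to
#' obtain smoothed reconstructions; with all coefficients intact the round
#' trip reproduces the input to near machine precision.
#'
#' @param dec A `"wavedec"` object.
#' @return Numeric matrix with the original dimensions.
#' @export
row_waverec <- function(dec) {
  filt <- wavelet_filters(dec$wavelet)
  cur <- dec$approx
  for (k in rev(seq_len(dec$level))) {
    cur <- idwt_step(cur, dec$details[[k]], filt, dec$lengths[k])
  }
  cur
}

# Approximation-only reconstruction at each level 1..max_level: detail
# coefficients at scales 1..k are zeroed, so level k is a progressively
# smoother version of the input.  Returns a list of matrices.
row_smooth_levels <- function(X, max_level, wavelet = "sym8") {
  dec <- row_wavedec(X, max_level, wavelet)
  filt <- wavelet_filters(wavelet)
  out <- vector("list", max_level)
  # reconstruct from the deepest approximation downwards, zeroing details
  # as we go; level k result needs details k+1..L intact and 1..k zeroed
  for (k in seq_len(max_level)) {
    d <- dec
    for (j in seq_len(k)) d$details[[j]][] <- 0
    out[[k]] <- row_waverec(d)
  }
  out
}
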
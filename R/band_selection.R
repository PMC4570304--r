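#' Critical correlation at a two-sided significance level
#'
#' The |r| threshold whose two-sided p-value under the exact t transform
#' `t = r * sqrt((n-2) / (1-r^2))` with n-2 degrees of freedom equals
#' `alpha`. Bands whose correlation with the target exceeds this in
#' absolute value are "significant at alpha".
#'
#' @param n Sample count (>= 3).
#' @param alpha Two-sided significance level in (0, 1).
#' @return The critical correlation r* in [0, 1).
#' @export
critical_r <- function(n, alpha = 0.01) {
  if (n < 3) stop("critical_r needs n >= 3")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)")
  tq <- stats::qt(1 - alpha / 2, df = n - 2)
  tq / sqrt(n - 2 + tq^2)
}

#' Select effective bands by correlation strength
#'
#' Marks bands whose absolute correlation with the target exceeds either a
#' fixed threshold (`threshold = 0.40`, say) or the significance threshold
#' [critical_r()] (`alpha = 0.01`). Selection is sign-agnostic: strongly
#' negative bands count. Bands flagged excluded/incomputable are never
#' selected.
#'
#' @param x An `"occ_result"` from [build_occ()], or a tibble with columns
#'   `wavelength`, `r` (and optionally `computable`/`excluded`), e.g. one
#'   level of [band_correlations()].
#' @param threshold Absolute-correlation cutoff in (0, 1). Give exactly one
#'   of `threshold` and `alpha`.
#' @param alpha Two-sided significance level; requires `n`.
#' @param n Sample count behind the correlations (taken from an
#'   `"occ_result"` automatically).
#' @return A tibble with columns `wavelength`, `r`, `selected`, plus
#'   attributes `n_selected`, `criterion` and `warning_empty`.
#' @export
select_bands <- function(x, threshold = NULL, alpha = NULL, n = NULL) {
  if (inherits(x, "occ_result")) {
    tab <- x$occ
    tab$computable <- !tab$excluded
    if (is.null(n)) n <- x$n
  } else {
    tab <- tibble::as_tibble(x)
    if (!all(c("wavelength", "r") %in% names(tab))) {
      stop("need columns wavelength and r")
    }
    if (!"computable" %in% names(tab)) {
      tab$computable <- if ("excluded" %in% names(tab)) !tab$excluded
                        else !is.na(tab$r)
    }
  }
  if (is.null(threshold) + is.null(alpha) != 1L) {
    stop("give exactly one of threshold or alpha")
  }
  if (!is.null(alpha)) {
    if (is.null(n)) stop("alpha criterion needs the sample count n")
    thr <- critical_r(n, alpha)
    criterion <- list(type = "significance", alpha = alpha, n = n,
                      threshold = thr)
  } else {
    if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0,1)")
    thr <- threshold
    criterion <- list(type = "absolute", threshold = thr)
  }
  sel <- tab$computable & !is.na(tab$r) & abs(tab$r) > thr
  out <- tibble::tibble(
    wavelength = tab$wavelength, r = tab$r, selected = sel
  )
  attr(out, "n_selected") <- sum(sel)
  attr(out, "criterion") <- criterion
  attr(out, "warning_empty") <- sum(sel) == 0L
  if (sum(sel) == 0L) {
    warning("band selection is empty (max |r| = ",
            round(max(abs(tab$r), na.rm = TRUE), 4), ", threshold ",
            round(thr, 4), ")")
  }
  out
}

#' Write / read a band mask as two-column CSV
#'
#' @param selection Output of [select_bands()].
#' @param path CSV path (`wavelength,selected`).
#' @export
write_band_mask <- function(selection, path) {
  utils::write.csv(
    data.frame(wavelength = selection$wavelength,
               selected = selection$selected),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' @rdname write_band_mask
#' @return `read_band_mask()`: tibble with columns `wavelength`, `selected`.
#' @export
read_band_mask <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  tibble::tibble(wavelength = as.numeric(df$wavelength),
                 selected = as.logical(df$selected))
}
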
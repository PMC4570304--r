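#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang %||% .data
NULL

#' Tidy a PLS model
#'
#' @param x A `"pls_model"`.
#' @param ... Unused.
#' @return Tibble with one row per band: `term` (band index), `estimate`
#'   (regression coefficient on the centred scale).
#' @method tidy pls_model
#' @export
tidy.pls_model <- function(x, ...) {
  tibble::tibble(term = seq_along(x$beta), estimate = x$beta)
}

#' @rdname tidy.pls_model
#' @return `glance()`: one-row tibble with `ncomp`, `n`, `r2_cal`,
#'   `rmse_cal`.
#' @method glance pls_model
#' @export
glance.pls_model <- function(x, ...) {
  y <- x$fitted + x$F                 # F holds the final y residuals
  tibble::tibble(
    ncomp = x$ncomp,
    n = nrow(x$T),
    r2_cal = 1 - sum(x$F^2) / sum((y - mean(y))^2),
    rmse_cal = sqrt(mean(x$F^2))
  )
}

#' Tidy an ANFIS model
#'
#' @param x An `"anfis_model"`.
#' @param ... Unused.
#' @return Tibble with one row per (input, membership): `input`, `mf`,
#'   `a`, `b`, `c`.
#' @method tidy anfis_model
#' @export
tidy.anfis_model <- function(x, ...) {
  purrr::map_dfr(seq_len(x$n_inputs), function(j) {
    tibble::tibble(
      input = j, mf = seq_len(x$mfs_per_input),
      a = x$premise[j, , "a"], b = x$premise[j, , "b"],
      c = x$premise[j, , "c"]
    )
  })
}

#' @rdname tidy.anfis_model
#' @method glance anfis_model
#' @export
glance.anfis_model <- function(x, ...) {
  tibble::tibble(
    n_inputs = x$n_inputs,
    n_rules = nrow(x$rules),
    epochs_run = length(x$loss_trace %||% numeric()),
    rmse_cal = if (length(x$loss_trace)) utils::tail(x$loss_trace, 1)
               else NA_real_
  )
}

#' Plot spectra as wavelength profiles
#'
#' @param object A [spectra] object.
#' @param colour_by `"site"` or `"sample_id"`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot spectra
#' @export
autoplot.spectra <- function(object, colour_by = c("site", "sample_id"),
                             ...) {
  colour_by <- match.arg(colour_by)
  df <- as_tibble.spectra(object)
  if (colour_by == "site" && is.null(df$site)) colour_by <- "sample_id"
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$wavelength, y = .data$value,
    group = .data$sample_id, colour = .data[[colour_by]]
  )) +
    ggplot2::geom_line(alpha = 0.6, linewidth = 0.3) +
    ggplot2::labs(
      x = "wavelength (nm)",
      y = transform_tag(object),
      colour = colour_by
    ) +
    ggplot2::theme_minimal()
}

#' Plot the optimal correlative curve and level map
#'
#' @param object An `"occ_result"`.
#' @param ... Unused.
#' @return A ggplot with the winning signed correlation per band, coloured
#'   by the chosen decomposition level.
#' @method autoplot occ_result
#' @export
autoplot.occ_result <- function(object, ...) {
  df <- dplyr::filter(object$occ, !.data$excluded)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$wavelength, y = .data$r, colour = factor(.data$level)
  )) +
    ggplot2::geom_point(size = 0.3) +
    ggplot2::labs(
      x = "wavelength (nm)", y = "optimal correlation with TN",
      colour = "level"
    ) +
    ggplot2::theme_minimal()
}

#' Observed versus predicted TN for a fitted pipeline
#'
#' @param object A `"method_fit"` from [run_method()].
#' @param ... Unused.
#' @return A ggplot faceted by split.
#' @method autoplot method_fit
#' @export
autoplot.method_fit <- function(object, ...) {
  ggplot2::ggplot(object$predictions, ggplot2::aes(
    x = .data$observed, y = .data$predicted
  )) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$site), alpha = 0.7) +
    ggplot2::facet_wrap(~split) +
    ggplot2::labs(
      x = "observed TN (mg/kg)", y = "predicted TN (mg/kg)",
      title = object$cfg$method
    ) +
    ggplot2::theme_minimal()
}

#' ANFIS training loss trace
#'
#' @param model A trained `"anfis_model"`.
#' @return A ggplot of calibration RMSE per epoch.
#' @export
plot_loss_trace <- function(model) {
  df <- tibble::tibble(epoch = seq_along(model$loss_trace),
                       rmse = model$loss_trace)
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$rmse)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "calibration RMSE (mg/kg)") +
    ggplot2::theme_minimal()
}
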
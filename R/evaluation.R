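#' Calibration/validation accuracy metrics
#'
#' `R2 = 1 - SSres/SStot` (total sum of squares about the observed mean of
#' the evaluated set), `RMSE = sqrt(mean((yhat - y)^2))` in the units of
#' the target (mg/kg for TN), and `MRE = 100 * mean(|yhat - y| / y)` in
#' percent. Observed values must be strictly positive (MRE divides by
#' them). With zero-variance observations R2 is undefined and returned as
#' `NA`.
#'
#' @param y_obs Observed values (> 0).
#' @param y_pred Predicted values, aligned with `y_obs`.
#' @return A tibble with one row: `n`, `r2`, `rmse`, `mre`.
#' @export
regression_metrics <- function(y_obs, y_pred) {
  y_obs <- as.numeric(y_obs); y_pred <- as.numeric(y_pred)
  if (length(y_obs) != length(y_pred)) stop("length mismatch")
  if (length(y_obs) < 2) stop("need at least 2 observations")
  if (any(y_obs <= 0)) stop("observed values must be strictly positive")
  ss_res <- sum((y_obs - y_pred)^2)
  ss_tot <- sum((y_obs - mean(y_obs))^2)
  r2 <- if (ss_tot == 0) NA_real_ else 1 - ss_res / ss_tot
  tibble::tibble(
    n = length(y_obs),
    r2 = r2,
    rmse = sqrt(mean((y_pred - y_obs)^2)),
    mre = 100 * mean(abs(y_pred - y_obs) / y_obs)
  )
}

#' Per-split, per-site evaluation report
#'
#' One row per split ("calibration"/"validation") and site block, with an
#' "overall" block per split first. Sites with fewer than 2 samples get an
#' explicit row with `NA` metrics; an empty split yields an explicit
#' `n = 0` row rather than a silent omission.
#'
#' @param y_obs,y_pred Observed/predicted values for one split.
#' @param split Split label.
#' @param site Optional per-sample site labels.
#' @param meta Named list of model metadata (method, transform, ...)
#'   attached as the `"meta"` attribute.
#' @return A tibble with columns `split`, `site`, `n`, `r2`, `rmse`, `mre`,
#'   of class `"evaluation_report"`.
#' @export
evaluation_report <- function(y_obs, y_pred, split = "calibration",
                              site = NULL, meta = list()) {
  empty_row <- function(s, st, n) tibble::tibble(
    split = s, site = st, n = n,
    r2 = NA_real_, rmse = NA_real_, mre = NA_real_
  )
  if (length(y_obs) == 0) {
    out <- empty_row(split, "overall", 0L)
  } else {
    out <- dplyr::bind_cols(
      tibble::tibble(split = split, site = "overall"),
      regression_metrics(y_obs, y_pred)
    )
    if (!is.null(site)) {
      for (s in unique(site)) {
        idx <- site == s
        block <- if (sum(idx) >= 2) {
          dplyr::bind_cols(tibble::tibble(split = split, site = s),
                           regression_metrics(y_obs[idx], y_pred[idx]))
        } else {
          empty_row(split, s, sum(idx))
        }
        out <- dplyr::bind_rows(out, block)
      }
    }
  }
  out <- out[, c("split", "site", "n", "r2", "rmse", "mre")]
  attr(out, "meta") <- meta
  class(out) <- c("evaluation_report", class(out))
  out
}

#' Combine split reports
#'
#' @param ... `"evaluation_report"` tibbles (e.g. calibration and
#'   validation blocks); metadata of the first is kept.
#' @return A single `"evaluation_report"`.
#' @export
bind_reports <- function(...) {
  parts <- list(...)
  out <- dplyr::bind_rows(lapply(parts, function(p) {
    class(p) <- setdiff(class(p), "evaluation_report")
    p
  }))
  attr(out, "meta") <- attr(parts[[1]], "meta")
  class(out) <- c("evaluation_report", class(out))
  out
}

#' Save / load an evaluation report
#'
#' Writes both a machine-readable JSON (full precision, including
#' metadata) and a human-readable CSV next to it. `path` may end in
#' `.json` or be a stem; the CSV replaces the extension with `.csv`.
#' Reports round-trip losslessly through the JSON (values to 1e-12 or
#' better).
#'
#' @param report An `"evaluation_report"`.
#' @param path Output path or stem.
#' @export
save_report <- function(report, path) {
  stem <- sub("\\.(json|csv)$", "", path)
  obj <- list(
    meta = attr(report, "meta"),
    rows = as.data.frame(report)
  )
  jsonlite::write_json(obj, paste0(stem, ".json"), digits = NA,
                       auto_unbox = TRUE, null = "null")
  utils::write.csv(as.data.frame(report), paste0(stem, ".csv"),
                   row.names = FALSE)
  invisible(paste0(stem, ".json"))
}

#' @rdname save_report
#' @return `read_report()`: the restored `"evaluation_report"`.
#' @export
read_report <- function(path) {
  stem <- sub("\\.(json|csv)$", "", path)
  obj <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  rows <- tibble::as_tibble(obj$rows)
  for (col in c("n", "r2", "rmse", "mre")) {
    rows[[col]] <- as.numeric(rows[[col]])
  }
  rows$n <- as.integer(rows$n)
  attr(rows, "meta") <- obj$meta
  class(rows) <- c("evaluation_report", class(rows))
  rows
}

#' @export
print.evaluation_report <- function(x, ...) {
  meta <- attr(x, "meta")
  if (length(meta)) {
    cat("<evaluation_report> ",
        paste(names(meta), unlist(lapply(meta, format)), sep = "=",
              collapse = ", "), "\n", sep = "")
  }
  NextMethod()
}
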
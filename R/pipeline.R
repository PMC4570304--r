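#' Method configuration for the four comparison pipelines
#'
#' The four pipelines share one skeleton — spectral transform, denoising,
#' correlation-based band selection, PLS — and differ in the denoising
#' stage and the regressor: `PLS` and `CS` smooth every spectrum at one
#' fixed decomposition level, `LCM` and `LCMCS` assemble the per-band
#' optimal spectrum (OSP); `CS` and `LCMCS` feed the PLS latent scores
#' into an ANFIS, the others stop at the PLS prediction.
#'
#' @param method `"PLS"`, `"LCM"`, `"CS"` or `"LCMCS"`.
#' @param transform Spectral transform (see [transform_spectra()]).
#' @param denoise `"none"`, `"fixed_level"` or `"lcm_osp"`.
#' @param level Smoothing level for `denoise = "fixed_level"`.
#' @param selection Either `list(alpha = 0.01)` (per-band significance) or
#'   `list(threshold = 0.40)` (absolute correlation cutoff).
#' @param lvs Number of PLS latent variables, or `"auto"` to pick by
#'   calibration error ([choose_components()]).
#' @param mfs_per_input,epochs,learning_rate,patience ANFIS training
#'   settings (used by `CS`/`LCMCS` only).
#' @param wavelet,max_level Wavelet settings for the denoising stage.
#' @param leaky_occ If `TRUE`, learn the LCM level map on calibration and
#'   validation samples pooled (the ambiguous all-samples variant);
#'   default `FALSE` learns it on the calibration set only.
#' @return A list of class `"method_config"`.
#' @export
method_config <- function(method = c("PLS", "LCM", "CS", "LCMCS"),
                          transform = "FDR_LOG_INV",
                          denoise = c("lcm_osp", "fixed_level", "none"),
                          level = 5L,
                          selection = list(alpha = 0.01),
                          lvs = 5L,
                          mfs_per_input = 2L,
                          epochs = 100L,
                          learning_rate = 0.01,
                          patience = 20L,
                          wavelet = "sym8",
                          max_level = 5L,
                          leaky_occ = FALSE) {
  method <- match.arg(method)
  denoise <- match.arg(denoise)
  if (method %in% c("LCM", "LCMCS") && denoise != "lcm_osp") {
    stop(method, " requires denoise = \"lcm_osp\"")
  }
  if (method %in% c("PLS", "CS") && denoise == "lcm_osp") {
    stop(method, " uses fixed-level smoothing (or none), not the OSP")
  }
  if (!is.list(selection) ||
      is.null(selection$alpha) == is.null(selection$threshold)) {
    stop("selection must set exactly one of alpha or threshold")
  }
  structure(as.list(environment()), class = "method_config")
}

#' Presets mirroring the reference four-model comparison
#'
#' All four work on the first derivative of the reciprocal logarithm.
#' `pls`: level-5 fixed smoothing, significant bands (p < 0.01), 8 latent
#' variables. `lcm`: OSP denoising, significant bands, 8 latent variables.
#' `cs`: level-4 fixed smoothing, |r| > 0.40 bands, 5 latent variables
#' into ANFIS. `lcmcs`: OSP denoising, significant bands, 5 latent
#' variables into ANFIS.
#'
#' @param name `"pls"`, `"lcm"`, `"cs"` or `"lcmcs"`.
#' @return A `"method_config"`.
#' @export
preset_config <- function(name = c("pls", "lcm", "cs", "lcmcs")) {
  name <- match.arg(name)
  switch(name,
    pls = method_config("PLS", denoise = "fixed_level", level = 5L,
                        selection = list(alpha = 0.01), lvs = 8L),
    lcm = method_config("LCM", denoise = "lcm_osp",
                        selection = list(alpha = 0.01), lvs = 8L),
    cs = method_config("CS", denoise = "fixed_level", level = 4L,
                       selection = list(threshold = 0.40), lvs = 5L),
    lcmcs = method_config("LCMCS", denoise = "lcm_osp",
                          selection = list(alpha = 0.01), lvs = 5L)
  )
}

#' Stratified calibration/validation split
#'
#' With site labels, samples are split within each site; site counts of
#' 100/95/85 get the reference 55/50/45 calibration allocation, otherwise
#' calibration counts follow `cal_fraction` with largest-remainder
#' rounding. Without site labels, a plain random split of
#' `round(cal_fraction * n)` samples is drawn.
#'
#' @param n Sample count.
#' @param site Optional per-sample site labels.
#' @param seed Integer seed.
#' @param cal_counts Optional named per-site calibration counts,
#'   overriding the rules above.
#' @param cal_fraction Calibration fraction (default 150/280).
#' @return List with integer index vectors `cal` and `val`.
#' @export
split_calibration <- function(n, site = NULL, seed = 1L, cal_counts = NULL,
                              cal_fraction = 150 / 280) {
  set.seed(seed)
  if (is.null(site)) {
    cal <- sort(sample.int(n, round(cal_fraction * n)))
    return(list(cal = cal, val = setdiff(seq_len(n), cal)))
  }
  stopifnot(length(site) == n)
  tab <- table(site)
  if (is.null(cal_counts)) {
    if (length(tab) == 3 && setequal(as.integer(tab), c(100L, 95L, 85L))) {
      cal_counts <- c(`100` = 55L, `95` = 50L, `85` = 45L)[
        as.character(as.integer(tab))]
      names(cal_counts) <- names(tab)
    } else {
      raw <- cal_fraction * as.integer(tab)
      base <- floor(raw)
      rem <- round(cal_fraction * n) - sum(base)
      extra <- order(raw - base, decreasing = TRUE)[seq_len(max(rem, 0))]
      base[extra] <- base[extra] + 1L
      cal_counts <- stats::setNames(as.integer(base), names(tab))
    }
  }
  cal <- integer(0)
  for (s in names(tab)) {
    idx <- which(site == s)
    cal <- c(cal, sort(sample(idx, cal_counts[[s]])))
  }
  cal <- sort(cal)
  list(cal = cal, val = setdiff(seq_len(n), cal))
}

#' Run one pipeline end-to-end
#'
#' Transform, denoise (fixed level or calibration-learned OSP level map),
#' select effective bands on the calibration correlations, fit PLS, fit
#' the ANFIS regressor on the latent scores where the method calls for
#' it, and evaluate per split and site. No validation sample touches any
#' learned state: the level map, the band mask, the PLS centring/weights
#' and the ANFIS are all learned on calibration rows only (unless
#' `leaky_occ` deliberately pools them for the level map).
#'
#' @param x A [spectra] object, transform `"REF"`.
#' @param targets Targets tibble (`sample_id`, `tn`).
#' @param cfg A `"method_config"`.
#' @param seed Integer seed controlling the split and any training
#'   randomness.
#' @param split Optional precomputed list with `cal`/`val` index vectors.
#' @return An object of class `"method_fit"`: `report`
#'   (an [evaluation_report][evaluation_report()]), `predictions` tibble,
#'   `cfg`, `seed`, `split`, `selection`, `occ` (for OSP methods), `pls`,
#'   `anfis` (or `NULL`).
#' @export
run_method <- function(x, targets, cfg, seed = 1L, split = NULL) {
  stopifnot(is_spectra(x), inherits(cfg, "method_config"))
  y_all <- align_targets(x, targets)
  site <- sites(x)
  if (is.null(split)) {
    split <- split_calibration(nrow(x), site, seed)
  }
  set.seed(seed + 1L)
  tx <- transform_spectra(x, cfg$transform)
  cal_t <- spectra_subset(tx, split$cal)
  val_t <- spectra_subset(tx, split$val)
  y_cal <- y_all[split$cal]; y_val <- y_all[split$val]

  occ <- NULL
  if (cfg$denoise == "lcm_osp") {
    learn_s <- if (cfg$leaky_occ) tx else cal_t
    learn_y <- if (cfg$leaky_occ) y_all else y_cal
    stack <- decompose_stack(learn_s, cfg$wavelet, cfg$max_level)
    occ <- build_occ(stack, targets = learn_y)
    if (cfg$leaky_occ) {
      den_cal <- spectra_subset(occ$osp, split$cal)
      den_val <- spectra_subset(occ$osp, split$val)
    } else {
      den_cal <- occ$osp
      den_val <- apply_level_map(val_t, occ)
    }
    sel_profile <- occ
  } else if (cfg$denoise == "fixed_level") {
    den_cal <- stack_level(decompose_stack(cal_t, cfg$wavelet, cfg$max_level),
                           cfg$level)
    den_val <- stack_level(decompose_stack(val_t, cfg$wavelet, cfg$max_level),
                           cfg$level)
    r <- suppressWarnings(as.vector(stats::cor(unclass(den_cal), y_cal)))
    sel_profile <- tibble::tibble(
      wavelength = wavelengths(den_cal), r = r, computable = !is.na(r)
    )
  } else {
    den_cal <- cal_t; den_val <- val_t
    r <- suppressWarnings(as.vector(stats::cor(unclass(den_cal), y_cal)))
    sel_profile <- tibble::tibble(
      wavelength = wavelengths(den_cal), r = r, computable = !is.na(r)
    )
  }

  selection <- select_bands(
    sel_profile,
    threshold = cfg$selection$threshold,
    alpha = cfg$selection$alpha,
    n = length(y_cal)
  )
  if (attr(selection, "n_selected") == 0L) {
    stop(
      "no band passes the selection criterion (max |r| = ",
      round(max(abs(selection$r), na.rm = TRUE), 4), ")"
    )
  }
  mask <- selection$selected
  X_cal <- unclass(den_cal)[, mask, drop = FALSE]
  X_val <- unclass(den_val)[, mask, drop = FALSE]

  lvs <- cfg$lvs
  if (identical(lvs, "auto")) {
    lvs <- choose_components(X_cal, y_cal, max_comp = 15L)
    lvs <- max(lvs, 1L)
  }
  lvs <- min(as.integer(lvs), nrow(X_cal) - 1L, ncol(X_cal))
  pls <- pls_fit(X_cal, y_cal, lvs)

  anfis <- NULL
  if (cfg$method %in% c("CS", "LCMCS")) {
    # scores are standardised by calibration statistics before the ANFIS:
    # bell widths and the consequent least-squares problem are then on a
    # comparable scale across components
    S_cal <- pls_scores(pls, X_cal)
    S_val <- pls_scores(pls, X_val)
    s_mu <- colMeans(S_cal)
    s_sd <- pmax(apply(S_cal, 2, stats::sd), 1e-12)
    S_cal <- sweep(sweep(S_cal, 2, s_mu), 2, s_sd, "/")
    S_val <- sweep(sweep(S_val, 2, s_mu), 2, s_sd, "/")
    anfis <- anfis_fit(
      S_cal, y_cal,
      mfs_per_input = cfg$mfs_per_input, epochs = cfg$epochs,
      learning_rate = cfg$learning_rate, patience = cfg$patience
    )
    pred_cal <- anfis_forward(anfis, S_cal)
    pred_val <- anfis_forward(anfis, S_val)
  } else {
    pred_cal <- predict(pls, X_cal)
    pred_val <- predict(pls, X_val)
  }

  meta <- list(
    method = cfg$method, transform = cfg$transform, denoise = cfg$denoise,
    level = if (cfg$denoise == "fixed_level") cfg$level else NA,
    selection = if (!is.null(cfg$selection$alpha)) {
      paste0("p<", cfg$selection$alpha)
    } else {
      paste0("|r|>", cfg$selection$threshold)
    },
    n_bands = sum(mask), lvs = lvs, seed = seed
  )
  report <- bind_reports(
    evaluation_report(y_cal, pred_cal, "calibration",
                      if (!is.null(site)) site[split$cal], meta),
    evaluation_report(y_val, pred_val, "validation",
                      if (!is.null(site)) site[split$val])
  )
  split_lab <- rep(c("calibration", "validation"),
                   c(length(split$cal), length(split$val)))
  ids_ord <- c(sample_ids(x)[split$cal], sample_ids(x)[split$val])
  site_ord <- if (!is.null(site)) c(site[split$cal], site[split$val]) else NA
  preds <- tibble::tibble(
    sample_id = ids_ord,
    split = split_lab,
    site = site_ord,
    observed = c(y_cal, y_val),
    predicted = c(pred_cal, pred_val)
  )
  structure(
    list(
      report = report, predictions = preds, cfg = cfg, seed = seed,
      split = split, selection = selection, occ = occ, pls = pls,
      anfis = anfis
    ),
    class = "method_fit"
  )
}

#' @export
print.method_fit <- function(x, ...) {
  print(x$report)
  invisible(x)
}

#' Run and tabulate several pipeline configurations
#'
#' One row per configuration with overall calibration and validation
#' metrics, sorted by validation R2 (best first). A configuration that
#' fails is recorded as a row with `NA` metrics and the error message,
#' never an abort.
#'
#' @param x A [spectra] object (`"REF"`).
#' @param targets Targets tibble.
#' @param cfgs List of `"method_config"` objects (default: the four
#'   presets).
#' @param seed Integer seed; all configurations share the same split.
#' @return A tibble with columns `method`, `transform`, `denoise`,
#'   `n_bands`, `lvs`, `r2_cal`, `rmse_cal`, `mre_cal`, `r2_val`,
#'   `rmse_val`, `mre_val`, `error`; fits attached as attribute `"fits"`.
#' @export
compare_methods <- function(x, targets,
                            cfgs = lapply(c("pls", "lcm", "cs", "lcmcs"),
                                          preset_config),
                            seed = 1L) {
  if (length(cfgs) < 2) stop("compare_methods needs at least 2 configurations")
  split <- split_calibration(nrow(x), sites(x), seed)
  fits <- vector("list", length(cfgs))
  rows <- purrr::map_dfr(seq_along(cfgs), function(i) {
    cfg <- cfgs[[i]]
    res <- tryCatch(run_method(x, targets, cfg, seed, split),
                    error = function(e) e)
    if (inherits(res, "error")) {
      return(tibble::tibble(
        method = cfg$method, transform = cfg$transform,
        denoise = cfg$denoise, n_bands = NA_integer_, lvs = NA_integer_,
        r2_cal = NA_real_, rmse_cal = NA_real_, mre_cal = NA_real_,
        r2_val = NA_real_, rmse_val = NA_real_, mre_val = NA_real_,
        error = conditionMessage(res)
      ))
    }
    fits[[i]] <<- res
    rep <- res$report
    cal <- rep[rep$split == "calibration" & rep$site == "overall", ]
    val <- rep[rep$split == "validation" & rep$site == "overall", ]
    tibble::tibble(
      method = cfg$method, transform = cfg$transform, denoise = cfg$denoise,
      n_bands = attr(res$report, "meta")$n_bands,
      lvs = attr(res$report, "meta")$lvs,
      r2_cal = cal$r2, rmse_cal = cal$rmse, mre_cal = cal$mre,
      r2_val = val$r2, rmse_val = val$rmse, mre_val = val$mre,
      error = NA_character_
    )
  })
  out <- dplyr::arrange(rows, dplyr::desc(.data$r2_val))
  attr(out, "fits") <- fits
  out
}
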
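#' Construct a spectra object
#'
#' A `spectra` object is a samples-by-bands numeric matrix carrying a
#' wavelength axis, sample identifiers, optional site labels, and a tag
#' recording which spectral transform the values represent. Original
#' reflectance (`"REF"`) must lie in (0, 1]; transformed values are
#' unconstrained.
#'
#' @param values Numeric matrix, one row per sample, one column per band.
#' @param wavelengths Strictly increasing, uniformly spaced numeric vector
#'   of band centres in nm; length must equal `ncol(values)`.
#' @param sample_ids Character vector of unique sample identifiers
#'   (default `"s1"`, `"s2"`, ...).
#' @param site Optional character/factor vector of per-sample site labels
#'   (e.g. `"C"`, `"R"`, `"F"`).
#' @param transform One of `"REF"`, `"FDR"`, `"LOG_INV"`, `"FDR_LOG_INV"`.
#' @return An object of class `"spectra"`.
#' @seealso [read_spectra()], [transform_spectra()], [as_tibble.spectra()]
#' @export
spectra <- function(values, wavelengths, sample_ids = NULL, site = NULL,
                    transform = "REF") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  transform <- match.arg(transform, c("REF", "FDR", "LOG_INV", "FDR_LOG_INV"))
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(values)))
  sample_ids <- as.character(sample_ids)
  if (!is.null(site)) site <- as.character(site)
  out <- structure(
    values,
    wavelengths = as.numeric(wavelengths),
    sample_ids = sample_ids,
    site = site,
    transform = transform,
    class = c("spectra", "matrix", "array")
  )
  validate_spectra(out)
  out
}

#' @rdname spectra
#' @param x Object to test or validate.
#' @export
is_spectra <- function(x) inherits(x, "spectra")

#' @rdname spectra
#' @export
validate_spectra <- function(x) {
  wl <- wavelengths(x)
  if (length(wl) != ncol(x)) {
    stop("wavelength count (", length(wl), ") != band count (", ncol(x), ")")
  }
  if (anyDuplicated(wl)) {
    stop(
      "duplicate wavelengths at indices: ",
      paste(which(duplicated(wl)), collapse = ", ")
    )
  }
  if (length(wl) > 1) {
    d <- diff(wl)
    if (any(d <= 0)) {
      stop(
        "wavelengths not strictly increasing at indices: ",
        paste(which(d <= 0), collapse = ", ")
      )
    }
    if (max(d) - min(d) > 1e-9) {
      bad <- which(abs(d - d[1]) > 1e-9)
      stop(
        "non-uniform wavelength grid at indices: ",
        paste(utils::head(bad, 10), collapse = ", ")
      )
    }
  }
  ids <- sample_ids(x)
  if (length(ids) != nrow(x)) stop("sample_ids length != sample count")
  if (anyDuplicated(ids)) stop("duplicate sample_ids")
  st <- sites(x)
  if (!is.null(st) && length(st) != nrow(x)) stop("site length != sample count")
  if (identical(attr(x, "transform"), "REF")) {
    bad <- which(!(x > 0 & x <= 1), arr.ind = TRUE)
    if (nrow(bad) > 0) {
      stop(
        "reflectance outside (0,1] at sample ", ids[bad[1, 1]],
        ", band ", wl[bad[1, 2]], " nm (", nrow(bad), " cells total)"
      )
    }
  }
  if (anyNA(x)) stop("spectra contain missing values")
  invisible(x)
}

#' Accessors for spectra metadata
#'
#' @param x A `spectra` object.
#' @return `wavelengths()`: numeric vector of band centres (nm);
#'   `sample_ids()`: character vector; `sites()`: character vector or
#'   `NULL`; `transform_tag()`: the transform label.
#' @export
wavelengths <- function(x) attr(x, "wavelengths")

#' @rdname wavelengths
#' @export
sample_ids <- function(x) attr(x, "sample_ids")

#' @rdname wavelengths
#' @export
sites <- function(x) attr(x, "site")

#' @rdname wavelengths
#' @export
transform_tag <- function(x) attr(x, "transform")

# rebuild a spectra object with new values but the same axis/metadata
restamp <- function(template, values, transform = transform_tag(template)) {
  spectra(values, wavelengths(template), sample_ids(template),
          sites(template), transform)
}

#' @export
print.spectra <- function(x, ...) {
  wl <- wavelengths(x)
  cat(
    "<spectra> ", nrow(x), " samples x ", ncol(x), " bands [",
    wl[1], "-", wl[length(wl)], " nm], transform = ", transform_tag(x),
    if (!is.null(sites(x))) paste0(", sites: ",
      paste(names(table(sites(x))), table(sites(x)), sep = ":", collapse = " ")),
    "\n", sep = ""
  )
  invisible(x)
}

#' Convert spectra to a long tibble
#'
#' @importFrom tibble as_tibble
#' @param x A `spectra` object.
#' @param ... Unused.
#' @return A tibble with columns `sample_id`, `site` (if present),
#'   `wavelength`, `value`.
#' @method as_tibble spectra
#' @export
as_tibble.spectra <- function(x, ...) {
  out <- tibble::tibble(
    sample_id = rep(sample_ids(x), times = ncol(x)),
    wavelength = rep(wavelengths(x), each = nrow(x)),
    value = as.vector(unclass(x)[, , drop = FALSE])
  )
  st <- sites(x)
  if (!is.null(st)) {
    out <- dplyr::mutate(out,
      site = rep(st, times = ncol(x)), .after = "sample_id")
  }
  out
}

#' Read spectra from CSV
#'
#' Wide layout: header `sample_id,350,351,...`; one row per sample.
#' Long layout: columns `sample_id,wavelength,value` (plus optional `site`).
#' A `site` column is honoured in both layouts.
#'
#' @param path CSV file path.
#' @param layout `"wide"` or `"long"`.
#' @param transform Transform tag to stamp on the result (default `"REF"`).
#' @return A [spectra] object; sample order of first appearance preserved.
#' @export
read_spectra <- function(path, layout = c("wide", "long"), transform = "REF") {
  layout <- match.arg(layout)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (layout == "wide") {
    wl_cols <- names(df)[!names(df) %in% c("sample_id", "site")]
    wl <- suppressWarnings(as.numeric(wl_cols))
    if (anyNA(wl)) {
      stop("non-numeric wavelength columns: ",
           paste(wl_cols[is.na(wl)], collapse = ", "))
    }
    vals <- as.matrix(df[, wl_cols, drop = FALSE])
    check_numeric_cells(vals, df$sample_id, wl_cols)
    ord <- order(wl)
    spectra(vals[, ord, drop = FALSE], wl[ord],
            sample_ids = df$sample_id, site = df$site, transform = transform)
  } else {
    need <- c("sample_id", "wavelength", "value")
    if (!all(need %in% names(df))) {
      stop("long layout needs columns: ", paste(need, collapse = ", "))
    }
    if (!is.numeric(df$value) || !is.numeric(df$wavelength)) {
      bad <- which(is.na(suppressWarnings(as.numeric(df$value))))[1]
      stop("non-numeric cell in long CSV at row ", bad)
    }
    ids <- unique(df$sample_id)
    wl <- sort(unique(df$wavelength))
    vals <- matrix(NA_real_, length(ids), length(wl),
                   dimnames = list(ids, wl))
    vals[cbind(match(df$sample_id, ids), match(df$wavelength, wl))] <- df$value
    if (anyNA(vals)) stop("long CSV does not cover the full sample x band grid")
    site <- NULL
    if ("site" %in% names(df)) {
      site <- df$site[match(ids, df$sample_id)]
    }
    dimnames(vals) <- NULL
    spectra(vals, wl, sample_ids = ids, site = site, transform = transform)
  }
}

check_numeric_cells <- function(vals, ids, cols) {
  if (!is.numeric(vals)) {
    bad <- which(is.na(suppressWarnings(matrix(as.numeric(vals), nrow(vals)))) ,
                 arr.ind = TRUE)
    stop("non-numeric cell at row ", ids[bad[1, 1]], ", column ",
         cols[bad[1, 2]])
  }
  invisible(NULL)
}

#' Write spectra to CSV
#'
#' @param x A [spectra] object.
#' @param path Output CSV path.
#' @param layout `"wide"` or `"long"`.
#' @export
write_spectra <- function(x, path, layout = c("wide", "long")) {
  layout <- match.arg(layout)
  if (layout == "wide") {
    df <- data.frame(sample_id = sample_ids(x), check.names = FALSE)
    if (!is.null(sites(x))) df$site <- sites(x)
    m <- as.data.frame(unclass(x))
    names(m) <- format(wavelengths(x), trim = TRUE, scientific = FALSE)
    df <- cbind(df, m)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    utils::write.csv(as_tibble.spectra(x), path, row.names = FALSE,
                     quote = FALSE)
  }
  invisible(path)
}

#' Read / write a target-property table
#'
#' Targets are stored as a two-column CSV `sample_id,tn` (TN in mg/kg);
#' an optional `site` column is carried along.
#'
#' @param path CSV path.
#' @return A tibble with columns `sample_id`, `tn` (and `site` if present).
#' @export
read_targets <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "tn") %in% names(df))) {
    stop("targets CSV needs columns sample_id, tn")
  }
  tibble::as_tibble(df)
}

#' @rdname read_targets
#' @param targets Tibble with `sample_id` and `tn` columns.
#' @export
write_targets <- function(targets, path) {
  utils::write.csv(targets, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Align a target table to the sample order of a spectra object
#'
#' Matching is by `sample_id`, never by row position; any sample without a
#' target (or vice versa) is a hard error. TN values must be strictly
#' positive (relative errors divide by the observed value).
#'
#' @param x A [spectra] object.
#' @param targets Tibble with columns `sample_id`, `tn`.
#' @return Numeric TN vector in `x`'s row order.
#' @export
align_targets <- function(x, targets) {
  ids <- sample_ids(x)
  m <- match(ids, targets$sample_id)
  if (anyNA(m)) {
    stop("no target value for samples: ",
         paste(utils::head(ids[is.na(m)], 5), collapse = ", "))
  }
  extra <- setdiff(targets$sample_id, ids)
  if (length(extra) > 0) {
    stop("targets contain unknown samples: ",
         paste(utils::head(extra, 5), collapse = ", "))
  }
  y <- as.numeric(targets$tn[m])
  if (any(!is.finite(y)) || any(y <= 0)) {
    stop("TN values must be finite and strictly positive")
  }
  y
}

#' Subset spectra by sample index
#'
#' @param x A [spectra] object.
#' @param i Row (sample) indices or logical mask.
#' @return A [spectra] object with the selected samples.
#' @export
spectra_subset <- function(x, i) {
  st <- sites(x)
  spectra(unclass(x)[i, , drop = FALSE], wavelengths(x),
          sample_ids(x)[i], if (!is.null(st)) st[i], transform_tag(x))
}
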
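#' Fit a univariate PLS regression by NIPALS
#'
#' Sequential NIPALS extraction with X-deflation: both X and y are
#' mean-centred; at each step the weight vector `w_h` is the (normalised)
#' covariance direction `X' y`, scores `t_h = X w_h`, X-loading
#' `p_h = X' t_h / (t_h' t_h)`, y-loading `q_h = y' t_h / (t_h' t_h)`, and
#' X is deflated by `t_h p_h'`. With a univariate response the Y-side
#' scores are the deflated responses themselves and the inner coefficients
#' `b_h` regress them on `t_h`. The composite coefficient vector
#' `beta = W (P'W)^{-1} q` maps a centred spectrum directly to a centred
#' prediction, and `R = W (P'W)^{-1}` projects new spectra onto the latent
#' scores.
#'
#' @param X Numeric matrix, samples x selected bands.
#' @param y Numeric response vector (TN, mg/kg).
#' @param ncomp Number of latent variables, at most `min(nrow(X)-1, ncol(X))`.
#' @return An object of class `"pls_model"` with fields `x_mean`, `y_mean`,
#'   `W`, `P`, `Q`, `T`, `U`, `B`, `beta`, `R`, `E`, `F`, `Ed`, `ncomp`,
#'   `fitted`.
#' @export
pls_fit <- function(X, y, ncomp) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("X and y sizes differ")
  if (stats::sd(y) == 0) stop("response has zero variance")
  if (ncomp < 1 || ncomp > min(n - 1, p)) {
    stop("ncomp must be in 1..min(n-1, p) = ", min(n - 1, p))
  }
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  Xc <- sweep(X, 2, x_mean)
  yc <- y - y_mean
  if (all(abs(Xc) < 1e-300)) stop("X is constant after centring")
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp); U <- matrix(0, n, ncomp)
  Q <- numeric(ncomp); B <- numeric(ncomp)
  Xd <- Xc; yd <- yc
  for (h in seq_len(ncomp)) {
    w <- crossprod(Xd, yd)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-14) {
      stop("no covariance left to extract at component ", h,
           "; reduce ncomp")
    }
    w <- w / nw
    t_h <- Xd %*% w
    tt <- sum(t_h^2)
    p_h <- crossprod(Xd, t_h) / tt
    q_h <- sum(yc * t_h) / tt
    W[, h] <- w; P[, h] <- p_h; Tm[, h] <- t_h; Q[h] <- q_h
    U[, h] <- yd                    # univariate y: Y-scores are deflated y
    B[h] <- sum(yd * t_h) / tt      # inner regression of u_h on t_h
    Xd <- Xd - tcrossprod(t_h, p_h)
    yd <- yd - as.vector(t_h) * q_h
  }
  R <- W %*% solve(crossprod(P, W))
  beta <- as.vector(R %*% Q)
  fitted <- as.vector(Xc %*% beta) + y_mean
  structure(
    list(
      x_mean = x_mean, y_mean = y_mean, W = W, P = P, Q = Q, T = Tm, U = U,
      B = B, beta = beta, R = R, E = Xd, F = yd,
      Ed = U - sweep(Tm, 2, B, `*`), ncomp = ncomp, fitted = fitted
    ),
    class = "pls_model"
  )
}

#' @export
print.pls_model <- function(x, ...) {
  cat("<pls_model> ", length(x$beta), " bands, ", x$ncomp,
      " latent variables\n", sep = "")
  invisible(x)
}

#' Predict from a PLS model
#'
#' `yhat = (x - x_mean) . beta + y_mean`.
#'
#' @param object A `"pls_model"`.
#' @param newdata Matrix with the training band count, or a numeric vector.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.pls_model <- function(object, newdata, ...) {
  X <- if (is.vector(newdata)) matrix(newdata, nrow = 1) else as.matrix(newdata)
  if (ncol(X) != length(object$x_mean)) {
    stop("newdata has ", ncol(X), " columns; model expects ",
         length(object$x_mean))
  }
  as.vector(sweep(X, 2, object$x_mean) %*% object$beta) + object$y_mean
}

#' Latent-variable scores for new spectra
#'
#' `t = (x - x_mean) R` with `R = W (P'W)^{-1}`; on the calibration matrix
#' this reproduces the stored score matrix `T`.
#'
#' @param model A `"pls_model"`.
#' @param newdata Matrix (samples x training band count).
#' @return Matrix samples x `ncomp` of latent scores.
#' @export
pls_scores <- function(model, newdata) {
  X <- if (is.vector(newdata)) matrix(newdata, nrow = 1) else as.matrix(newdata)
  if (ncol(X) != length(model$x_mean)) {
    stop("newdata has ", ncol(X), " columns; model expects ",
         length(model$x_mean))
  }
  sweep(X, 2, model$x_mean) %*% model$R
}

#' Choose the number of latent variables from calibration error
#'
#' Fits 1..`max_comp` components and returns the smallest count after
#' which the relative improvement in calibration RMSE stays below `tol`
#' (first minimum within tolerance).
#'
#' @param X Calibration matrix.
#' @param y Calibration response.
#' @param max_comp Largest component count to consider.
#' @param tol Relative-improvement stopping tolerance (default 1e-6).
#' @return Integer component count.
#' @export
choose_components <- function(X, y, max_comp, tol = 1e-6) {
  max_comp <- min(max_comp, nrow(X) - 1, ncol(X))
  rmse_prev <- Inf
  for (h in seq_len(max_comp)) {
    fit <- tryCatch(pls_fit(X, y, h), error = function(e) NULL)
    if (is.null(fit)) return(max(h - 1L, 1L))  # no covariance left
    rmse <- sqrt(mean((fit$fitted - y)^2))
    if (is.finite(rmse_prev) &&
        (rmse_prev - rmse) <= tol * max(rmse_prev, .Machine$double.eps)) {
      return(h - 1L)
    }
    rmse_prev <- rmse
  }
  max_comp
}

#' Serialize / restore a PLS model as JSON
#'
#' @param model A `"pls_model"`.
#' @param path JSON path.
#' @export
write_pls_model <- function(model, path) {
  obj <- lapply(model, function(f) if (is.matrix(f)) list(
    dim = dim(f), data = as.vector(f)) else f)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_pls_model
#' @export
read_pls_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- lapply(obj, function(f) {
    if (is.list(f) && !is.null(f$dim)) matrix(f$data, f$dim[1], f$dim[2])
    else if (is.list(f)) unlist(f) else f
  })
  out$ncomp <- as.integer(out$ncomp)
  class(out) <- "pls_model"
  out
}
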
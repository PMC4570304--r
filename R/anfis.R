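#' Generalized bell membership function
#'
#' `mu(x) = 1 / (1 + ((x - c)/a)^(2b))`, evaluated as
#' `1 / (1 + (((x - c)/a)^2)^b)` so non-integer shape parameters are safe.
#' Equals 1 at the centre `x = c` and 0.5 at `x = c +/- a` for any `b`.
#'
#' @param x Numeric input (vectorised).
#' @param a Width (> 0): half-width at half-maximum.
#' @param b Shape (> 0): steepness of the shoulder.
#' @param c Centre.
#' @return Membership values in (0, 1].
#' @export
bell_membership <- function(x, a, b, c) {
  if (any(a <= 0) || any(b <= 0)) stop("bell parameters a and b must be > 0")
  u <- ((x - c) / a)^2
  1 / (1 + u^b)
}

#' Initialize a Takagi-Sugeno ANFIS on a grid partition
#'
#' One generalized bell membership set per input per partition cell:
#' centres spread evenly over each input's training range, widths `a` set
#' to half the centre spacing (or half the range for a single MF), shape
#' `b = 2`. Rules are all combinations of one MF per input
#' (`mfs_per_input ^ n_inputs`); each rule carries a first-order linear
#' consequent (one coefficient per input plus an intercept), initialised
#' to zero and set by the first least-squares pass of [anfis_fit()].
#'
#' @param X Training input matrix (samples x inputs), e.g. PLS scores.
#' @param mfs_per_input Memberships per input (default 2).
#' @param jitter Standard deviation of optional seed-controlled relative
#'   jitter on the initial centres (default 0 = none).
#' @return An object of class `"anfis_model"`.
#' @export
anfis_init <- function(X, mfs_per_input = 2L, jitter = 0) {
  X <- as.matrix(X)
  d <- ncol(X); m <- as.integer(mfs_per_input)
  if (m < 1L) stop("mfs_per_input must be >= 1")
  rng <- apply(X, 2, range)
  prem <- array(0, dim = c(d, m, 3), dimnames = list(NULL, NULL, c("a", "b", "c")))
  for (j in seq_len(d)) {
    lo <- rng[1, j]; hi <- rng[2, j]
    span <- max(hi - lo, 1e-6)
    centres <- if (m == 1L) (lo + hi) / 2 else seq(lo, hi, length.out = m)
    if (jitter > 0) centres <- centres + stats::rnorm(m, 0, jitter * span)
    width <- if (m == 1L) span / 2 else (centres[2] - centres[1]) / 2
    prem[j, , "a"] <- max(width, 1e-6)
    prem[j, , "b"] <- 2
    prem[j, , "c"] <- centres
  }
  rules <- as.matrix(expand.grid(rep(list(seq_len(m)), d)))
  dimnames(rules) <- NULL
  structure(
    list(
      n_inputs = d, mfs_per_input = m, premise = prem, rules = rules,
      consequent = matrix(0, nrow(rules), d + 1L),
      input_ranges = rng, notes = character()
    ),
    class = "anfis_model"
  )
}

#' @export
print.anfis_model <- function(x, ...) {
  cat("<anfis_model> ", x$n_inputs, " inputs x ", x$mfs_per_input,
      " bell MFs -> ", nrow(x$rules), " rules\n", sep = "")
  invisible(x)
}

# memberships for all inputs/MFs: returns list over inputs of n x m matrices
anfis_memberships <- function(model, X) {
  lapply(seq_len(model$n_inputs), function(j) {
    p <- model$premise[j, , , drop = FALSE]
    out <- vapply(seq_len(model$mfs_per_input), function(i) {
      bell_membership(X[, j], p[1, i, "a"], p[1, i, "b"], p[1, i, "c"])
    }, numeric(nrow(X)))
    matrix(out, nrow = nrow(X))
  })
}

# firing strengths: n x n_rules product over inputs of the chosen MF
anfis_firing <- function(model, X, mu = anfis_memberships(model, X)) {
  n <- nrow(X)
  w <- matrix(1, n, nrow(model$rules))
  for (j in seq_len(model$n_inputs)) {
    w <- w * mu[[j]][, model$rules[, j], drop = FALSE]
  }
  w
}

#' ANFIS forward pass
#'
#' The five layers of the Takagi-Sugeno network: (1) bell memberships per
#' input, (2) rule firing strengths as the product of the memberships the
#' rule names, (3) normalisation of firing strengths across rules,
#' (4) each rule's linear consequent weighted by its normalised strength,
#' (5) the sum over rules.
#'
#' @param model An `"anfis_model"`.
#' @param X Input matrix (samples x `n_inputs`) or a single input vector.
#' @param detail If `TRUE`, also return firing strengths and the
#'   normalised strengths.
#' @return Numeric predictions, or (with `detail`) a list with `pred`,
#'   `w`, `wbar`.
#' @export
anfis_forward <- function(model, X, detail = FALSE) {
  if (is.vector(X)) X <- matrix(X, nrow = 1)
  X <- as.matrix(X)
  if (ncol(X) != model$n_inputs) {
    stop("input has ", ncol(X), " columns; model expects ", model$n_inputs)
  }
  w <- anfis_firing(model, X)
  sw <- rowSums(w)
  if (any(sw <= 0 | !is.finite(sw))) {
    stop("zero or non-finite total firing strength (degenerate premises)")
  }
  wbar <- w / sw
  f <- tcrossprod(cbind(X, 1), model$consequent)  # n x rules: rule outputs
  pred <- rowSums(wbar * f)
  if (detail) list(pred = pred, w = w, wbar = wbar) else pred
}

#' @export
predict.anfis_model <- function(object, newdata, ...) {
  anfis_forward(object, newdata)
}

# design matrix for the global consequent LSE: n x (rules * (d+1)),
# blocks wbar_r * [x, 1]
anfis_design <- function(model, X, wbar) {
  d <- model$n_inputs
  Xa <- cbind(X, 1)
  nr <- nrow(model$rules)
  out <- matrix(0, nrow(X), nr * (d + 1L))
  for (r in seq_len(nr)) {
    out[, (r - 1L) * (d + 1L) + seq_len(d + 1L)] <- wbar[, r] * Xa
  }
  out
}

ridge_solve <- function(Phi, y, lambda) {
  sv <- svd(Phi)
  uty <- crossprod(sv$u, y)
  sv$v %*% (uty * sv$d / (sv$d^2 + lambda))
}

# least-squares pass for all consequents with premises frozen.  With a
# grid partition the design is routinely rank-deficient (rule count times
# inputs+1 exceeds the sample count) and an unregularised solve would
# interpolate the calibration noise, so the solve is ridge-regularised
# with the penalty chosen by 5-fold cross-validation over a grid spanning
# the singular spectrum; `lambda` is the floor of that search.  An exactly
# representable target (e.g. one linear in the inputs) drives the
# cross-validation error to zero at the floor, so such targets are still
# fit to numerical precision by the first pass.
anfis_lse <- function(model, X, y, wbar, lambda = 1e-8, lambda_fixed = NULL) {
  Phi <- anfis_design(model, X, wbar)
  n <- nrow(Phi)
  if (is.null(lambda_fixed)) {
    d1sq <- max(svd(Phi, nu = 0, nv = 0)$d[1]^2, 1e-300)
    lams <- unique(pmax(10^seq(log10(d1sq) - 12, log10(d1sq),
                               length.out = 25), lambda))
    folds <- rep_len(seq_len(5), n)
    sse <- numeric(length(lams))
    for (f in seq_len(5)) {
      tr <- folds != f
      sv <- svd(Phi[tr, , drop = FALSE])
      uty <- crossprod(sv$u, y[tr])
      for (i in seq_along(lams)) {
        b <- sv$v %*% (uty * sv$d / (sv$d^2 + lams[i]))
        sse[i] <- sse[i] + sum((Phi[!tr, , drop = FALSE] %*% b - y[!tr])^2)
      }
    }
    l_best <- lams[which.min(sse)]
  } else {
    l_best <- lambda_fixed
  }
  coefs <- ridge_solve(Phi, y, l_best)
  attr(coefs, "ridge") <- TRUE
  attr(coefs, "lambda") <- l_best
  matrix(coefs, nrow(model$rules), model$n_inputs + 1L, byrow = TRUE)
}

# analytic gradient of mean squared error wrt premise parameters (a, b, c);
# returns array shaped like model$premise
anfis_premise_grad <- function(model, X, y) {
  n <- nrow(X); d <- model$n_inputs; m <- model$mfs_per_input
  mu <- anfis_memberships(model, X)
  w <- anfis_firing(model, X, mu)
  sw <- rowSums(w)
  wbar <- w / sw
  f <- tcrossprod(cbind(X, 1), model$consequent)
  pred <- rowSums(wbar * f)
  err <- 2 * (pred - y) / n                  # d(MSE)/d(pred)
  # d pred / d w_r = (f_r - pred) / sum(w)
  dpred_dw <- (f - pred) / sw                # n x rules
  grad <- array(0, dim = dim(model$premise),
                dimnames = dimnames(model$premise))
  for (j in seq_len(d)) {
    a <- model$premise[j, , "a"]; b <- model$premise[j, , "b"]
    cc <- model$premise[j, , "c"]
    for (i in seq_len(m)) {
      rules_i <- which(model$rules[, j] == i)
      muji <- mu[[j]][, i]
      # d w_r / d mu = w_r / mu (mu > 0 for bell functions)
      dwsum <- rowSums(dpred_dw[, rules_i, drop = FALSE] *
                         w[, rules_i, drop = FALSE]) / muji
      z <- (X[, j] - cc[i]) / a[i]
      u <- z^2
      ub <- u^b[i]
      dmu_du <- ifelse(u > 0, -b[i] * ub / u / (1 + ub)^2, 0)
      dmu_da <- dmu_du * (-2 * u / a[i])
      dmu_dc <- dmu_du * (-2 * z / a[i])
      dmu_db <- ifelse(u > 0, -(ub * log(pmax(u, 1e-300))) / (1 + ub)^2, 0)
      common <- err * dwsum
      grad[j, i, "a"] <- sum(common * dmu_da)
      grad[j, i, "b"] <- sum(common * dmu_db)
      grad[j, i, "c"] <- sum(common * dmu_dc)
    }
  }
  grad
}

#' Hybrid training of an ANFIS
#'
#' Each epoch (i) freezes the premises and solves the global linear
#' least-squares problem for all rule consequents on the design matrix of
#' normalised-firing-weighted inputs (ridge regularisation with
#' `lambda = 1e-8` when the design is rank-deficient), then (ii) takes one
#' gradient-descent step on the bell premise parameters against the mean
#' squared error, with step-halving whenever a step would increase the
#' loss, so the recorded loss trace is non-increasing. Widths and shapes
#' are clamped to a positive floor. A linear target is therefore fit
#' exactly by the very first least-squares pass, whatever the premise
#' initialisation.
#'
#' @param X Training inputs (samples x inputs), e.g. PLS latent scores.
#' @param y Training response.
#' @param mfs_per_input Bell memberships per input (default 2).
#' @param epochs Training epochs (default 100).
#' @param learning_rate Initial premise step size (default 0.01).
#' @param patience Early stop after this many non-improving epochs
#'   (default 20).
#' @param lambda Ridge fallback strength for the consequent solve.
#' @param model Optionally a pre-built `"anfis_model"` (e.g. with jittered
#'   initialisation); otherwise initialised from `X`.
#' @return A trained `"anfis_model"` with a `loss_trace` field (RMSE per
#'   epoch) and `notes` recording any ridge fallback.
#' @export
anfis_fit <- function(X, y, mfs_per_input = 2L, epochs = 100L,
                      learning_rate = 0.01, patience = 20L, lambda = 1e-8,
                      model = NULL) {
  X <- as.matrix(X); y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("X and y sizes differ")
  if (epochs < 1L) stop("epochs must be >= 1")
  if (is.null(model)) model <- anfis_init(X, mfs_per_input)
  ridge_used <- FALSE
  loss <- numeric(0)
  best <- Inf; stall <- 0L
  lr <- learning_rate
  lam <- NULL   # CV-selected on the first pass, then held fixed
  for (ep in seq_len(epochs)) {
    fw <- anfis_forward(model, X, detail = TRUE)
    cons <- anfis_lse(model, X, y, fw$wbar, lambda, lambda_fixed = lam)
    lam <- attr(cons, "lambda")
    ridge_used <- ridge_used || isTRUE(attr(cons, "ridge"))
    model$consequent <- cons
    cur <- sqrt(mean((anfis_forward(model, X) - y)^2))
    # premise step with halving safeguard (consequents held fixed)
    grad <- anfis_premise_grad(model, X, y)
    gnorm <- sqrt(sum(grad^2))
    if (gnorm > 0) {
      step <- lr
      for (try in 1:12) {
        cand <- model
        cand$premise <- model$premise - step * grad / gnorm
        cand$premise[, , "a"] <- pmax(cand$premise[, , "a"], 1e-6)
        cand$premise[, , "b"] <- pmax(cand$premise[, , "b"], 1e-6)
        cand_rmse <- sqrt(mean((anfis_forward(cand, X) - y)^2))
        if (cand_rmse <= cur) {
          model <- cand
          cur <- cand_rmse
          break
        }
        step <- step / 2
      }
    }
    loss <- c(loss, cur)
    if (cur < best - 1e-12) { best <- cur; stall <- 0L } else stall <- stall + 1L
    if (stall >= patience) break
    if (cur < 1e-13) break
  }
  # final consequent refresh so premises and consequents are consistent
  fw <- anfis_forward(model, X, detail = TRUE)
  cons <- anfis_lse(model, X, y, fw$wbar, lambda, lambda_fixed = lam)
  ridge_used <- ridge_used || isTRUE(attr(cons, "ridge"))
  final <- model; final$consequent <- cons
  final_rmse <- sqrt(mean((anfis_forward(final, X) - y)^2))
  if (final_rmse <= cur) { model <- final; cur <- final_rmse }
  loss <- c(loss, cur)
  if (ridge_used) {
    model$notes <- c(model$notes,
      "consequent LSE rank-deficient; ridge (lambda=1e-8) used")
  }
  model$loss_trace <- loss
  model
}

#' Serialize / restore an ANFIS model as JSON
#'
#' @param model An `"anfis_model"`.
#' @param path JSON path.
#' @export
write_anfis_model <- function(model, path) {
  obj <- list(
    n_inputs = model$n_inputs, mfs_per_input = model$mfs_per_input,
    premise = list(dim = dim(model$premise), data = as.vector(model$premise)),
    rules = list(dim = dim(model$rules), data = as.vector(model$rules)),
    consequent = list(dim = dim(model$consequent),
                      data = as.vector(model$consequent)),
    input_ranges = list(dim = dim(model$input_ranges),
                        data = as.vector(model$input_ranges)),
    notes = model$notes, loss_trace = model$loss_trace
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_anfis_model
#' @export
read_anfis_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  prem <- array(obj$premise$data, dim = obj$premise$dim,
                dimnames = list(NULL, NULL, c("a", "b", "c")))
  out <- list(
    n_inputs = as.integer(obj$n_inputs),
    mfs_per_input = as.integer(obj$mfs_per_input),
    premise = prem,
    rules = matrix(obj$rules$data, obj$rules$dim[1], obj$rules$dim[2]),
    consequent = matrix(obj$consequent$data, obj$consequent$dim[1],
                        obj$consequent$dim[2]),
    input_ranges = matrix(obj$input_ranges$data, obj$input_ranges$dim[1],
                          obj$input_ranges$dim[2]),
    notes = obj$notes %||% character(),
    loss_trace = obj$loss_trace
  )
  class(out) <- "anfis_model"
  out
}
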
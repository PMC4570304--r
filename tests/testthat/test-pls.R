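test_that("one predictor, one component reduces to simple least squares", {
  set.seed(1)
  x <- matrix(rnorm(40), 40, 1)
  y <- 2 + 3 * x[, 1] + rnorm(40, 0, 0.1)
  fit <- pls_fit(x, y, 1)
  ols <- lm(y ~ x)
  expect_equal(predict(fit, x), unname(fitted(ols)), tolerance = 1e-10)
})

test_that("full-component PLS equals ordinary least squares on full-rank X", {
  set.seed(2)
  for (i in 1:5) {
    X <- matrix(rnorm(40 * 6), 40, 6)
    y <- X %*% rnorm(6) + rnorm(40, 0, 0.2)
    fit <- pls_fit(X, y, 6)
    beta_ols <- solve(crossprod(scale(X, scale = FALSE)),
                      crossprod(scale(X, scale = FALSE), y - mean(y)))
    expect_equal(as.vector(fit$beta), as.vector(beta_ols), tolerance = 1e-8)
  }
})

test_that("noiseless linear response is fit exactly within its rank", {
  set.seed(3)
  X <- matrix(rnorm(30 * 10), 30, 10)
  y <- as.vector(X %*% c(1, -1, rep(0, 8))) + 5
  fit <- pls_fit(X, y, 10)   # exact within at most rank(X) components
  expect_equal(fit$fitted, y, tolerance = 1e-8)
})

test_that("scores are orthogonal, reproduce T, and predictions centre correctly", {
  set.seed(4)
  X <- matrix(rnorm(50 * 20), 50, 20)
  y <- X %*% rnorm(20) + rnorm(50)
  fit <- pls_fit(X, y, 5)
  G <- crossprod(fit$T)
  offdiag <- abs(G[upper.tri(G)])
  norms <- sqrt(diag(G))
  expect_lt(max(offdiag / tcrossprod(norms)[upper.tri(G)]), 1e-8)
  expect_equal(pls_scores(fit, X), fit$T, tolerance = 1e-10)
  expect_equal(predict(fit, fit$x_mean), fit$y_mean, tolerance = 1e-10)
  expect_identical(predict(fit, X), fit$fitted)
  # fitted values reproduce the deflation recursion through beta
  expect_equal(as.vector(sweep(X, 2, fit$x_mean) %*% fit$beta) + fit$y_mean,
               fit$fitted, tolerance = 1e-10)
})

test_that("predictions match an independent reference implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(5)
  for (i in 1:20) {
    n <- 30; p <- 20
    ncomp <- sample(1:5, 1)
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("V", 1:p)))
    y <- X %*% rnorm(p) + rnorm(n)
    Xn <- matrix(rnorm(8 * p), 8, p, dimnames = list(NULL, paste0("V", 1:p)))
    fit <- pls_fit(X, y, ncomp)
    ref <- mixOmics::pls(X, y, ncomp = ncomp, mode = "regression",
                         scale = FALSE)
    ref_pred <- predict(ref, Xn)$predict[, 1, ncomp]
    expect_equal(unname(predict(fit, Xn)), unname(ref_pred),
                 tolerance = 1e-8)
  }
})

test_that("calibration RMSE never increases with more components", {
  set.seed(6)
  X <- matrix(rnorm(40 * 15), 40, 15)
  y <- X %*% rnorm(15) + rnorm(40)
  rmse <- vapply(1:10, function(h) {
    sqrt(mean((pls_fit(X, y, h)$fitted - y)^2))
  }, numeric(1))
  expect_true(all(diff(rmse) <= 1e-10))
})

test_that("component choice stops early on noise and spans the rank when exact", {
  set.seed(7)
  # rank-2 spectra (two latent factors): two components reconstruct a
  # noiseless linear response, so the search stops there
  scores2 <- matrix(rnorm(60 * 2), 60, 2)
  load2 <- matrix(rnorm(2 * 10), 2, 10)
  X <- scores2 %*% load2
  y2 <- as.vector(X %*% rnorm(10))
  expect_lte(choose_components(X, y2, 8), 2L)
  # on pure noise every extra component still shaves calibration error a
  # little, so the documented coarse tolerance is what halts the search
  hits <- vapply(1:10, function(i) {
    set.seed(100 + i)
    Xn <- matrix(rnorm(40 * 12), 40, 12)
    yn <- rnorm(40)
    choose_components(Xn, yn, 10, tol = 0.05)
  }, integer(1))
  expect_lt(mean(hits), 6)
})

test_that("model JSON serialisation round-trips predictions", {
  set.seed(8)
  X <- matrix(rnorm(30 * 8), 30, 8)
  y <- X %*% rnorm(8) + rnorm(30)
  fit <- pls_fit(X, y, 3)
  f <- withr::local_tempfile(fileext = ".json")
  write_pls_model(fit, f)
  back <- read_pls_model(f)
  expect_equal(predict(back, X), predict(fit, X), tolerance = 1e-12)
})

test_that("degenerate fits are rejected", {
  X <- matrix(rnorm(20 * 5), 20, 5)
  expect_error(pls_fit(X, rep(3, 20), 2), "zero variance")
  expect_error(pls_fit(X, rnorm(20), 10), "ncomp")
  expect_error(predict(pls_fit(X, rnorm(20), 2), matrix(0, 1, 4)), "columns")
})
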
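test_that("each stack level is genuinely smoother: its fine detail is gone", {
  set.seed(11)
  s <- tiny_spectra(n = 3, nb = 256, seed = 11)
  stack <- decompose_stack(s, max_level = 3)
  for (k in 1:3) {
    lev <- unclass(stack$levels[[k]])
    redec <- row_wavedec(lev, k)
    # boundary coefficients feel the symmetric extension; the interior
    # of every zeroed detail band must vanish
    fine <- sum(vapply(redec$details[1:k], function(d) {
      int <- 17:(ncol(d) - 16)
      sum(abs(d[, int]))
    }, numeric(1)))
    total <- sum(abs(lev))
    expect_lt(fine / total, 1e-8)
    expect_equal(dim(lev), dim(unclass(s)))
    expect_equal(wavelengths(stack$levels[[k]]), wavelengths(s))
  }
})

test_that("smoothing raises correlation with a clean signal under fine noise", {
  set.seed(3)
  n <- 60; nb <- 256
  wl <- seq(350, by = 1, length.out = nb)
  g <- rnorm(n)
  shape <- exp(-(wl - 470)^2 / (2 * 25^2))
  clean <- 0.4 + 0.05 * outer(g, shape)
  noise <- matrix(rnorm(n * nb, 0, 0.02), n, nb)
  dec <- row_wavedec(noise, 2)
  dec$approx[] <- 0
  s <- spectra(pmin(pmax(clean + row_waverec(dec), 1e-6), 1), wl)
  stack <- decompose_stack(s, max_level = 2)
  j <- which.max(shape)
  r0 <- abs(cor(unclass(stack$base)[, j], g))
  r2 <- abs(cor(unclass(stack$levels[[2]])[, j], g))
  expect_gt(r2, r0)
})

test_that("band correlations: self-correlation, affine invariance, flags", {
  s <- tiny_spectra(n = 10, nb = 64, seed = 5)
  stack <- decompose_stack(s, max_level = 2)
  y <- unclass(s)[, 7]
  prof <- band_correlations(stack, y)
  expect_equal(prof$r[prof$level == 0][7], 1)
  prof2 <- band_correlations(stack, 3 * y + 2)
  expect_equal(prof$r, prof2$r, tolerance = 1e-12)
  expect_true(all(abs(prof$r[prof$computable]) <= 1 + 1e-12))
  expect_error(band_correlations(decompose_stack(tiny_spectra(n = 2),
                                               max_level = 2),
                                 c(1, 2)), "at least 3")
})

test_that("zero-variance bands are flagged incomputable, not NaN", {
  wl <- 350:477
  vals <- cbind(matrix(0.5, 8, 4), matrix(runif(8 * 124, 0.2, 0.8), 8))
  s <- spectra(vals, wl)
  stack <- decompose_stack(s, max_level = 2)
  prof <- band_correlations(stack, rnorm(8) + 10)
  lev0 <- prof[prof$level == 0, ]
  expect_false(any(lev0$computable[1:4]))
  expect_true(all(is.na(lev0$r[1:4])))
  expect_false(anyNA(lev0$r[lev0$computable]))
})

test_that("occ takes the per-band argmax with ties to the lowest level", {
  s <- tiny_spectra(n = 12, nb = 64, seed = 9)
  stack <- decompose_stack(s, max_level = 2)
  y <- rnorm(12) + 10
  prof <- band_correlations(stack, y)
  occ <- build_occ(stack, prof)
  wide <- matrix(prof$r, ncol = 3)  # bands x levels (0..2)
  expect_equal(occ$level_map, apply(abs(wide), 1, which.max) - 1L)
  expect_equal(abs(occ$occ$r), apply(abs(wide), 1, max), tolerance = 1e-12)
  # |occ r| never below the initial spectrum's |r|
  expect_true(all(abs(occ$occ$r) >= abs(wide[, 1]) - 1e-12))
  # osp columns equal the winning level's columns exactly
  for (k in 0:2) {
    sel <- occ$level_map == k
    if (any(sel)) {
      expect_identical(unclass(occ$osp)[, sel],
                       unclass(lcmcs:::stack_level(stack, k))[, sel])
    }
  }
  # forced tie: profiles equal at every level -> level 0 wins
  tied <- prof
  tied$r <- rep(prof$r[prof$level == 0], 3)
  occ_t <- build_occ(stack, tied)
  expect_true(all(occ_t$level_map == 0L))
})

test_that("level maps transfer to new spectra and are idempotent on training", {
  s <- tiny_spectra(n = 10, nb = 128, seed = 2)
  stack <- decompose_stack(s, max_level = 3)
  occ <- build_occ(stack, targets = rnorm(10) + 12)
  expect_spectra_equal(apply_level_map(s, occ), occ$osp, tol = 1e-12)
  s_new <- tiny_spectra(n = 4, nb = 128, seed = 8)
  expect_spectra_equal(apply_level_map(s_new, rep(0L, 128)), s_new)
  all3 <- apply_level_map(s_new, rep(3L, 128), max_level = 3)
  direct <- decompose_stack(s_new, max_level = 3)$levels[[3]]
  expect_spectra_equal(all3, direct, tol = 1e-12)
  expect_error(apply_level_map(tiny_spectra(nb = 64), occ), "grid")
})
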
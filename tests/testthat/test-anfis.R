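test_that("bell membership hits its closed-form anchor points", {
  expect_equal(bell_membership(3, a = 2, b = 5, c = 3), 1)
  for (b in c(0.5, 1, 2, 7)) {
    expect_equal(bell_membership(5, a = 2, b = b, c = 3), 0.5)
    expect_equal(bell_membership(1, a = 2, b = b, c = 3), 0.5)
  }
  expect_equal(bell_membership(2, a = 1, b = 2, c = 0), 1 / 17,
               tolerance = 1e-15)
  expect_error(bell_membership(1, a = 0, b = 1, c = 0), "> 0")
  expect_error(bell_membership(1, a = 1, b = -1, c = 0), "> 0")
})

test_that("normalised firing strengths always sum to one", {
  set.seed(1)
  X <- matrix(rnorm(1000 * 3), 1000, 3)
  m <- anfis_init(X, mfs_per_input = 2)
  m$consequent[] <- rnorm(length(m$consequent))
  fw <- anfis_forward(m, X, detail = TRUE)
  expect_lt(max(abs(rowSums(fw$wbar) - 1)), 1e-12)
})

test_that("a single rule makes the network its own linear consequent", {
  set.seed(2)
  X <- matrix(rnorm(50 * 2), 50, 2)
  m <- anfis_init(X, mfs_per_input = 1)
  m$consequent[1, ] <- c(2, -3, 0.5)
  expect_equal(anfis_forward(m, X),
               as.vector(X %*% c(2, -3) + 0.5), tolerance = 1e-12)
})

test_that("forward pass matches a hand-unrolled two-input computation", {
  # 2 inputs x 2 MFs with hand-set parameters; every layer written out
  # with scalar arithmetic, independent of the package's vectorised path
  m <- anfis_init(matrix(c(0, 1, 0, 1), 2, 2), mfs_per_input = 2)
  m$premise[1, , "a"] <- c(1, 2);   m$premise[2, , "a"] <- c(1.5, 0.5)
  m$premise[1, , "b"] <- c(2, 3);   m$premise[2, , "b"] <- c(1, 2)
  m$premise[1, , "c"] <- c(-1, 1);  m$premise[2, , "c"] <- c(0, 2)
  cons <- matrix(c(
    1, -1, 0.5,
    2, 0, -0.25,
    -1, 3, 0,
    0.5, 0.5, 1
  ), 4, 3, byrow = TRUE)
  m$consequent <- cons
  x <- c(0.3, -0.7)
  mu <- function(x, a, b, c) 1 / (1 + (((x - c) / a)^2)^b)
  muA <- c(mu(x[1], 1, 2, -1), mu(x[1], 2, 3, 1))
  muB <- c(mu(x[2], 1.5, 1, 0), mu(x[2], 0.5, 2, 2))
  # rule grid in the same order as expand.grid: A index varies fastest
  w <- c(muA[1] * muB[1], muA[2] * muB[1], muA[1] * muB[2], muA[2] * muB[2])
  wbar <- w / sum(w)
  f <- cons %*% c(x, 1)
  expect_equal(anfis_forward(m, x), sum(wbar * f), tolerance = 1e-12)
})

test_that("rule order permutation leaves the forward output unchanged", {
  set.seed(3)
  X <- matrix(rnorm(20 * 2), 20, 2)
  m <- anfis_init(X, 2)
  m$consequent[] <- rnorm(length(m$consequent))
  perm <- sample(nrow(m$rules))
  m2 <- m
  m2$rules <- m$rules[perm, , drop = FALSE]
  m2$consequent <- m$consequent[perm, , drop = FALSE]
  expect_equal(anfis_forward(m, X), anfis_forward(m2, X), tolerance = 1e-12)
})

test_that("a linear target is fit by the first least-squares pass alone", {
  set.seed(4)
  for (i in 1:3) {
    X <- matrix(rnorm(80 * 3), 80, 3)
    y <- as.vector(X %*% c(1.5, -2, 0.7)) + 3
    m <- anfis_init(X, 2, jitter = if (i > 1) 0.3 else 0)
    fw <- anfis_forward(m, X, detail = TRUE)
    m$consequent <- lcmcs:::anfis_lse(m, X, y, fw$wbar)
    expect_lt(sqrt(mean((anfis_forward(m, X) - y)^2)), 1e-5)
  }
})

test_that("the analytic premise gradient matches finite differences", {
  set.seed(5)
  X <- matrix(rnorm(25 * 2), 25, 2)
  y <- rnorm(25)
  m <- anfis_init(X, 2)
  m$consequent[] <- rnorm(length(m$consequent), 0, 0.3)
  gr <- lcmcs:::anfis_premise_grad(m, X, y)
  h <- 1e-6
  loss <- function(mod) mean((anfis_forward(mod, X) - y)^2)
  for (j in 1:2) for (i in 1:2) for (p in c("a", "b", "c")) {
    mp <- m; mp$premise[j, i, p] <- mp$premise[j, i, p] + h
    mm <- m; mm$premise[j, i, p] <- mm$premise[j, i, p] - h
    num <- (loss(mp) - loss(mm)) / (2 * h)
    expect_equal(unname(gr[j, i, p]), num, tolerance = 1e-4)
  }
})

test_that("hybrid training: loss trace non-increasing, improves on nonlinear targets", {
  set.seed(6)
  for (trial in 1:3) {
    X <- matrix(rnorm(150 * 2), 150, 2)
    y <- X[, 1] * X[, 2] + 0.5 * X[, 1] + rnorm(150, 0, 0.05)
    fit <- anfis_fit(X, y, epochs = 15)
    expect_true(all(diff(fit$loss_trace) <= 1e-10))
    lin <- lm(y ~ X)
    expect_lt(utils::tail(fit$loss_trace, 1),
              sqrt(mean(resid(lin)^2)))
    expect_true(all(fit$premise[, , "a"] > 0))
    expect_true(all(fit$premise[, , "b"] > 0))
  }
})

test_that("duplicating every training row leaves the fit unchanged", {
  set.seed(7)
  X <- matrix(rnorm(60 * 2), 60, 2)
  y <- sin(X[, 1]) + rnorm(60, 0, 0.1)
  f1 <- anfis_fit(X, y, epochs = 5)
  f2 <- anfis_fit(rbind(X, X), c(y, y), epochs = 5)
  expect_equal(f1$premise, f2$premise, tolerance = 1e-8)
  expect_equal(anfis_forward(f1, X), anfis_forward(f2, X), tolerance = 1e-6)
})

test_that("model JSON serialisation round-trips predictions", {
  set.seed(8)
  X <- matrix(rnorm(50 * 2), 50, 2)
  y <- X[, 1]^2 + rnorm(50, 0, 0.1)
  fit <- anfis_fit(X, y, epochs = 3)
  f <- withr::local_tempfile(fileext = ".json")
  write_anfis_model(fit, f)
  back <- read_anfis_model(f)
  expect_equal(anfis_forward(back, X), anfis_forward(fit, X),
               tolerance = 1e-12)
})
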
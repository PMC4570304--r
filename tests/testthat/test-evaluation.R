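test_that("metrics match hand arithmetic and the degenerate anchors", {
  m <- regression_metrics(c(10, 20), c(11, 18))
  expect_equal(m$rmse, sqrt((1 + 4) / 2), tolerance = 1e-12)
  expect_equal(m$mre, 100 * (0.1 + 0.1) / 2, tolerance = 1e-12)
  y <- c(8, 12, 15, 9)
  exact <- regression_metrics(y, y)
  expect_equal(c(exact$r2, exact$rmse, exact$mre), c(1, 0, 0))
  konst <- regression_metrics(y, rep(mean(y), 4))
  expect_equal(konst$r2, 0)
  expect_true(is.na(regression_metrics(rep(5, 3), c(4, 5, 6))$r2))
  expect_error(regression_metrics(c(-1, 2), c(1, 2)), "positive")
})

test_that("metrics are invariant to sample order", {
  set.seed(1)
  y <- runif(20, 5, 20); p <- y + rnorm(20)
  o <- sample(20)
  expect_equal(regression_metrics(y, p), regression_metrics(y[o], p[o]))
})

test_that("site blocks recombine into the overall RMSE by pooled squares", {
  set.seed(2)
  site <- rep(c("C", "R", "F"), times = c(10, 8, 7))
  y <- runif(25, 5, 20); p <- y + rnorm(25)
  rep_ <- evaluation_report(y, p, "validation", site)
  overall <- rep_[rep_$site == "overall", ]
  per <- rep_[rep_$site != "overall", ]
  expect_equal(sum(per$n), overall$n)
  pooled <- sqrt(sum(per$n * per$rmse^2) / overall$n)
  expect_equal(pooled, overall$rmse, tolerance = 1e-12)
})

test_that("single-site data makes the site block equal the overall block", {
  y <- runif(10, 5, 20); p <- y + rnorm(10)
  rep_ <- evaluation_report(y, p, "calibration", rep("C", 10))
  expect_equal(unlist(rep_[rep_$site == "C", c("n", "r2", "rmse", "mre")]),
               unlist(rep_[rep_$site == "overall", c("n", "r2", "rmse", "mre")]))
})

test_that("degenerate blocks are explicit: empty split and n < 2 sites", {
  empty <- evaluation_report(numeric(0), numeric(0), "validation")
  expect_equal(empty$n, 0L)
  expect_true(all(is.na(empty[, c("r2", "rmse", "mre")])))
  y <- runif(5, 5, 20)
  rep_ <- evaluation_report(y, y + 0.1, "validation",
                            c("C", "C", "C", "C", "F"))
  frow <- rep_[rep_$site == "F", ]
  expect_equal(frow$n, 1L)
  expect_true(is.na(frow$rmse))
})

test_that("reports round-trip through JSON/CSV losslessly", {
  set.seed(3)
  y <- runif(30, 5, 20); p <- y + rnorm(30)
  site <- rep(c("C", "R", "F"), 10)
  rep_ <- bind_reports(
    evaluation_report(y, p, "calibration", site,
                      meta = list(method = "LCMCS", lvs = 5L)),
    evaluation_report(y[1:12], p[1:12], "validation", site[1:12])
  )
  stem <- withr::local_tempfile()
  save_report(rep_, stem)
  expect_true(file.exists(paste0(stem, ".json")))
  expect_true(file.exists(paste0(stem, ".csv")))
  back <- read_report(stem)
  for (col in c("r2", "rmse", "mre")) {
    expect_equal(back[[col]], rep_[[col]], tolerance = 1e-12)
  }
  expect_equal(back$n, rep_$n)
  expect_equal(attr(back, "meta")$method, "LCMCS")
  # per-site labelled blocks present for all three sites
  expect_setequal(unique(back$site), c("overall", "C", "R", "F"))
})
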
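test_that("generation is exactly reproducible by seed", {
  g1 <- generate_spectra(tiny_config(), seed = 42)
  g2 <- generate_spectra(tiny_config(), seed = 42)
  expect_identical(unclass(g1$spectra), unclass(g2$spectra))
  expect_identical(g1$targets, g2$targets)
  g3 <- generate_spectra(tiny_config(), seed = 43)
  expect_false(identical(unclass(g1$spectra), unclass(g3$spectra)))
})

test_that("outputs satisfy the container invariants and stated conditions", {
  gen <- generate_spectra(synthetic_config(), seed = 1)
  s <- gen$spectra
  expect_equal(dim(s), c(280L, 2151L))
  expect_true(all(unclass(s) > 0 & unclass(s) <= 1))
  expect_equal(as.integer(table(sites(s))[c("C", "R", "F")]),
               c(100L, 95L, 85L))
  expect_true(all(gen$targets$tn >= 7 & gen$targets$tn <= 19))
  expect_identical(validate_spectra(s), s)
})

test_that("reflectance decreases with TN", {
  gen <- generate_spectra(synthetic_config(), seed = 2)
  mean_refl <- rowMeans(unclass(gen$spectra))
  expect_lt(cor(gen$targets$tn, mean_refl), -0.5)
})

test_that("clean channel outcorrelates the noisy channel at feature bands", {
  cfg <- synthetic_config(burr_amplitude = 0.008, burr_slope = 0,
                          white_noise = 0)
  gen <- generate_spectra(cfg, seed = 3)
  tn <- gen$targets$tn
  for (j in gen$truth$signal_bands[c(1, 25, 50, 80)]) {
    r_clean <- abs(cor(gen$truth$clean[, j], tn))
    r_noisy <- abs(cor(unclass(gen$spectra)[, j], tn))
    expect_gte(r_clean, r_noisy - 1e-12)
  }
})

test_that("noiseless linear configuration is recovered almost perfectly by PLS", {
  cfg <- synthetic_config(
    burr_amplitude = 0, white_noise = 0, nonlinearity = 0,
    smooth_nuisance = 0, baseline_wander = 0, confounder_sd = 0,
    confounder_depth = 0, swir_interference = 0
  )
  gen <- generate_spectra(cfg, seed = 4)
  cfg_m <- method_config("PLS", transform = "LOG_INV",
                         denoise = "none", lvs = "auto")
  fit <- run_method(gen$spectra, gen$targets, cfg_m, seed = 4)
  val <- fit$report[fit$report$split == "validation" &
                      fit$report$site == "overall", ]
  expect_gt(val$r2, 0.99)
})

test_that("smoothing helps at feature-adjacent bands on default noise", {
  cfg <- synthetic_config(burr_amplitude = 0.008, burr_slope = 0,
                          white_noise = 0)
  gen <- generate_spectra(cfg, seed = 5)
  tx <- transform_spectra(gen$spectra, "FDR_LOG_INV")
  stack <- decompose_stack(tx, max_level = 3)
  tn <- gen$targets$tn
  sb <- gen$truth$signal_bands
  r0 <- abs(as.vector(cor(unclass(stack$base)[, sb], tn)))
  r3 <- abs(as.vector(cor(unclass(stack$levels[[3]])[, sb], tn)))
  expect_gt(mean(r3), mean(r0))
})

test_that("fixtures land on disk, reload cleanly, and regenerate identically", {
  dir <- withr::local_tempdir()
  paths <- make_fixture("tiny", dir, seed = 9)
  s <- read_spectra(paths["spectra"], "wide")
  expect_equal(dim(s), c(12L, 64L))
  expect_identical(validate_spectra(s), s)
  targets <- read_targets(paths["targets"])
  expect_equal(nrow(targets), 12L)
  expect_equal(align_targets(s, targets), targets$tn, tolerance = 1e-12)
  truth <- jsonlite::read_json(paths["truth"], simplifyVector = TRUE)
  expect_equal(truth$noise_scale, 1L)
  b1 <- readBin(paths["spectra"], "raw", file.size(paths["spectra"]))
  dir2 <- withr::local_tempdir()
  paths2 <- make_fixture("tiny", dir2, seed = 9)
  b2 <- readBin(paths2["spectra"], "raw", file.size(paths2["spectra"]))
  expect_identical(b1, b2)
})

test_that("field-shaped fixture honours the reference split design", {
  gen <- generate_spectra(synthetic_config(), seed = 6)
  split <- split_calibration(280, sites(gen$spectra), seed = 6)
  expect_length(split$cal, 150)
  expect_length(split$val, 130)
  st <- sites(gen$spectra)
  expect_equal(as.integer(table(st[split$cal])[c("C", "R", "F")]),
               c(55L, 50L, 45L))
  expect_equal(as.integer(table(st[split$val])[c("C", "R", "F")]),
               c(45L, 45L, 40L))
})

test_that("overdriven parameters trip the clipping guard", {
  cfg <- synthetic_config(white_noise = 0.5)
  expect_error(generate_spectra(cfg, seed = 1), "rescale")
})
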
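# small deterministic builders shared across test files

tiny_spectra <- function(n = 5, nb = 64, seed = 1, transform = "REF") {
  set.seed(seed)
  wl <- seq(350, by = 1, length.out = nb)
  base <- 0.3 + 0.1 * sin(seq(0, pi, length.out = nb))
  vals <- pmin(pmax(t(replicate(n, base + rnorm(nb, 0, 0.01))), 1e-6), 1)
  spectra(vals, wl, sample_ids = paste0("s", seq_len(n)),
          site = rep(c("C", "R", "F"), length.out = n), transform = transform)
}

# read the frozen reference DWT fixture (generated with an independent
# reference wavelet implementation)
dwt_oracle <- function() {
  lines <- readLines(test_path("sym8-dwt-oracle.csv"))
  vals <- lapply(lines, function(l) as.numeric(strsplit(l, ",")[[1]][-1]))
  names(vals) <- vapply(lines, function(l) strsplit(l, ",")[[1]][1], "")
  vals
}

expect_spectra_equal <- function(a, b, tol = 1e-12) {
  expect_equal(wavelengths(a), wavelengths(b))
  expect_lt(max(abs(unclass(a) - unclass(b))), tol)
}
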
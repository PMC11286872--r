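test_that("radial Gabor kernel: center value, symmetry, spectral peak", {
  k <- radialGaborKernel(0.05, period = 0.863, sigmaF = 0.5,
                         removeDC = FALSE)
  c0 <- (nrow(k) + 1) / 2
  expect_equal(k[c0, c0], 1 / (2 * pi * 0.5^2))       # envelope peak * cos(0)
  expect_equal(as.vector(k),
               as.vector(k[rev(seq_len(nrow(k))), rev(seq_len(ncol(k)))]))
  kdc <- radialGaborKernel(0.05, period = 0.863, sigmaF = 0.5)
  expect_lt(abs(sum(kdc)), 1e-10)                      # strictly bandpass
  # FFT power spectrum peaks at the carrier frequency (narrowband kernel,
  # where the envelope-induced peak shift is negligible)
  kn <- radialGaborKernel(0.05, period = 0.863, sigmaF = 2)
  n <- 1024
  pad <- matrix(0, n, n); pad[seq_len(nrow(kn)), seq_len(ncol(kn))] <- kn
  P <- Mod(fft(pad))^2
  f <- c(0:(n / 2), -(n / 2 - 1):-1) / (n * 0.05)
  fr <- sqrt(outer(f^2, f^2, "+"))
  fPk <- fr[which.max(P)]
  expect_equal(fPk, 1 / 0.863, tolerance = 0.05)
})

test_that("map synthesis is deterministic and refinement-invariant", {
  sh1 <- makeCorticalSheet(c(20, 27), c(-3.5, 3.5), spacing = 0.2, seed = 7)
  sh1b <- makeCorticalSheet(c(20, 27), c(-3.5, 3.5), spacing = 0.2, seed = 7)
  expect_identical(sh1@theta, sh1b@theta)
  expect_identical(sh1@wOd, sh1b@wOd)
  expect_identical(sh1@deltaOnOff, sh1b@deltaOnOff)
  # same seed, finer grid: same large-scale structure
  sh2 <- makeCorticalSheet(c(20, 27), c(-3.5, 3.5), spacing = 0.1, seed = 7)
  sub <- sh2@wOd[seq(1, nrow(sh2@wOd), 2), seq(1, ncol(sh2@wOd), 2)]
  expect_gt(cor(as.vector(sh1@wOd), as.vector(sub)), 0.9)
  # different seed: different maps
  sh3 <- makeCorticalSheet(c(20, 27), c(-3.5, 3.5), spacing = 0.2, seed = 8)
  expect_lt(abs(cor(as.vector(sh1@wOd), as.vector(sh3@wOd))), 0.5)
})

test_that("synthesized maps have the stated marginal distributions", {
  sh <- makeCorticalSheet(c(20, 32), c(-6, 6), spacing = 0.1, seed = 5)
  expect_true(all(sh@theta > -pi / 2 - 1e-9 & sh@theta <= pi / 2 + 1e-9))
  expect_true(all(sh@wOd >= 0 & sh@wOd <= 1))
  expect_true(all(sh@wOnOff >= 0 & sh@wOnOff <= 1))
  expect_true(all(is.finite(sh@deltaOnOff)))
  expect_true(all(sh@sigmaRf > 0))
  # ocular dominance ~ uniform on [0, 1]
  set.seed(1)
  sub <- sample(as.vector(sh@wOd), 1e4)
  expect_gt(suppressWarnings(ks.test(sub, "punif")$p.value), 0.01)
  # |delta| / RF area ~ Exp(rate 2): mean 0.5 within 5%
  aRf <- pi * sh@sigmaRf * (sh@sigmaRf / 4)
  expect_equal(mean(abs(sh@deltaOnOff) / aRf), 0.5, tolerance = 0.05)
  # visual positions equal the inverse map of the grid
  w <- complex(real = sh@xmm[5], imaginary = sh@ymm[9])
  z <- cortexToVisual(w, sh@map)
  expect_equal(sh@zRe[5, 9], Re(z), tolerance = 1e-9)
  expect_equal(sh@zIm[5, 9], Im(z), tolerance = 1e-9)
})

test_that("column-period estimation recovers a known sinusoid and scales with the filter", {
  x <- seq(0, 30, 0.1)
  m <- outer(sin(2 * pi * x / 0.863), rep(1, 81))
  expect_equal(estimateColumnPeriod(m, 0.1), 0.863, tolerance = 0.04)
  expect_error(estimateColumnPeriod(matrix(1, 50, 50), 0.1), "flat")
  # halving the target period halves the measured period
  shA <- makeCorticalSheet(c(20, 32), c(-6, 6), spacing = 0.05, seed = 9,
                           noiseSpacing = 0.05)
  shB <- makeCorticalSheet(c(20, 32), c(-6, 6), spacing = 0.05, seed = 9,
                           odPeriod = 0.863 / 2, noiseSpacing = 0.05)
  pA <- estimateColumnPeriod(shA@wOd, 0.05)
  pB <- estimateColumnPeriod(shB@wOd, 0.05)
  expect_equal(pA / pB, 2, tolerance = 0.2)
})

test_that("receptive-field size grows linearly and the alternate preset is larger", {
  expect_equal(rfSize(0), 0.16)
  expect_equal(rfSize(5), 0.56)
  ecc <- seq(0, 40, 0.5)
  expect_true(all(rfSize(ecc, "meta") > rfSize(ecc, "keliris")))
})

test_that("undersized extents are rejected", {
  expect_error(makeCorticalSheet(c(20, 21), c(-4, 4), spacing = 0.1),
               "extent")
})
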
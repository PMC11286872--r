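test_that("receptive fields are unit-mass two-subunit Gaussians", {
  sh <- testSheet(ecc = 3)
  i <- 10; j <- 12
  sig <- sh@sigmaRf[i, j]
  half <- 5 * sig + abs(sh@deltaOnOff[i, j])
  xd <- seq(sh@zRe[i, j] - half, sh@zRe[i, j] + half, by = sig / 40)
  yd <- seq(sh@zIm[i, j] - half, sh@zIm[i, j] + half, by = sig / 40)
  rf <- buildRf(sh, i, j, xd, yd)
  px <- (sig / 40)^2
  expect_equal(sum(rf$on) * px, 1, tolerance = 1e-3)
  expect_equal(sum(rf$off) * px, 1, tolerance = 1e-3)
  # subunit centers are deltaOnOff apart along the short axis
  sep <- sqrt(sum((rf$centers["on", ] - rf$centers["off", ])^2))
  expect_equal(sep, abs(sh@deltaOnOff[i, j]), tolerance = 1e-12)
  # classification rule
  expect_equal(rf$class,
               if (abs(sh@deltaOnOff[i, j]) > sig / 2) "simple" else "complex")
  # delta = 0: subunits coincide (complex-cell limit)
  sh0 <- sh; sh0@deltaOnOff[i, j] <- 0
  rf0 <- buildRf(sh0, i, j, xd, yd)
  expect_equal(rf0$on, rf0$off)
  expect_equal(rf0$class, "complex")
})

test_that("zero current renders a zero field; point sources land at the mapped position", {
  sh <- testSheet(ecc = 3)
  cur <- matrix(0, length(sh@xmm), length(sh@ymm))
  sp0 <- renderSpatialField(sh, cur)
  expect_true(all(sp0$field == 0))
  expect_equal(sp0$nActive, 0L)
  # single stimulated location at the patch center
  i <- which.min(abs(sh@xmm - eccCortexX(3))); j <- which.min(abs(sh@ymm))
  cur[i, j] <- 10
  sp <- renderSpatialField(sh, cur)
  X <- matrix(sp$xdeg, length(sp$xdeg), length(sp$ydeg))
  Y <- matrix(sp$ydeg, length(sp$xdeg), length(sp$ydeg), byrow = TRUE)
  f <- abs(sp$field)
  cx <- sum(X * f) / sum(f); cy <- sum(Y * f) / sum(f)
  z <- cortexToVisual(complex(real = sh@xmm[i], imaginary = sh@ymm[j]),
                      sh@map)
  expect_lt(Mod(complex(real = cx - Re(z), imaginary = cy - Im(z))), 0.1)
})

test_that("pure-ON vs pure-OFF sheets give intensity ratio 1 : 0.8", {
  sh <- testSheet(ecc = 3)
  el <- electrode("e", eccCortexX(3), 0, 0.25)
  cur <- currentField(el, sh, 100)
  shOn <- sh; shOn@wOnOff[] <- 1
  shOff <- sh; shOff@wOnOff[] <- 0
  spOn <- renderSpatialField(shOn, cur)
  spOff <- renderSpatialField(shOff, cur, xdeg = spOn$xdeg,
                              ydeg = spOn$ydeg)
  expect_equal(max(abs(spOff$field)) / max(abs(spOn$field)), 0.8,
               tolerance = 0.05)
  expect_lte(max(spOff$field), 0)   # OFF percepts are dark
})

test_that("single-electrode movies are spatiotemporally separable before compression", {
  sh <- testSheet(ecc = 3)
  el <- electrode("e", eccCortexX(3), 0, 0.25, s = 1)
  tr <- pulseTrain(2000, 0.25, 50, 0.1)
  mv <- renderPercept(sh, el, tr, calParams, dtFrame = 50)
  expect_true(all(abs(mv@frames) <= calParams@sOut))
  # invert the compression; frame ratios must be a constant field
  pre <- atanh(mv@frames / calParams@sOut) * calParams@pDiv
  k1 <- which.max(apply(abs(pre), 3, max))
  k2 <- max(k1 - 2, 1)
  r <- pre[, , k1] / pre[, , k2]
  mask <- abs(pre[, , k1]) > 1e-3 * max(abs(pre[, , k1]))
  expect_lt(diff(range(r[mask])) / mean(r[mask]), 1e-6)
})

test_that("a one-electrode schedule reproduces renderPercept exactly", {
  sh <- testSheet(ecc = 3)
  el <- electrode("e", eccCortexX(3), 0, 0.25, s = 1)
  tr <- pulseTrain(2000, 0.25, 100, 0.05)
  mv1 <- renderSequence(sh, list(list(electrode = el, train = tr,
                                      onsetMs = 0)),
                        calParams, dtFrame = 25)
  mv2 <- renderPercept(sh, el, tr, calParams, dtFrame = 25,
                       xdeg = mv1@xdeg, ydeg = mv1@ydeg)
  k <- seq_len(min(length(mv1@timesMs), length(mv2@timesMs)))
  expect_equal(mv1@frames[, , k], mv2@frames[, , k], tolerance = 1e-12)
})

test_that("simultaneous stimulation superposes drives before compression", {
  sh <- testSheet(ecc = 3)
  e1 <- electrode("a", eccCortexX(3) - 0.8, 0, 0.25, s = 1)
  e2 <- electrode("b", eccCortexX(3) + 0.8, 0, 0.25, s = 1)
  tr <- pulseTrain(2000, 0.25, 100, 0.05)
  both <- renderSequence(sh, list(
    list(electrode = e1, train = tr, onsetMs = 0),
    list(electrode = e2, train = tr, onsetMs = 0)), calParams, dtFrame = 25)
  k <- which.max(apply(abs(both@frames), 3, max))
  preBoth <- atanh(both@frames[, , k] / calParams@sOut) * calParams@pDiv
  # manual superposition of the two per-electrode drives on the same grid
  f1 <- renderSpatialField(sh, currentField(e1, sh, tr@amplitude),
                           xdeg = both@xdeg, ydeg = both@ydeg)$field
  f2 <- renderSpatialField(sh, currentField(e2, sh, tr@amplitude),
                           xdeg = both@xdeg, ydeg = both@ydeg)$field
  unitTr <- pulseTrain(1, tr@pulseWidth, tr@frequency, tr@trainDuration)
  d <- simulateTemporal(unitTr, calParams)$r2
  dv <- approx(d$time_ms, d$value, xout = both@timesMs[k])$y / tr@amplitude
  preSum <- (f1 + f2) * dv * tr@amplitude
  expect_equal(max(abs(preSum - preBoth)) / max(abs(preBoth)), 0,
               tolerance = 1e-6)
})

test_that("sequential stimulation orders the drive peaks with the schedule", {
  p25 <- temporalParams(tau2 = 25)  # fast-memory variant for clean handoff
  tr <- pulseTrain(1, 0.25, 200, 0.05)
  d <- simulateTemporal(tr, p25)$r2
  onsets <- c(0, 100, 200)
  drives <- lapply(onsets, function(on)
    approx(d$time_ms + on, d$value, xout = seq(0, 500, 5),
           yleft = 0, yright = 0)$y)
  peaks <- vapply(drives, which.max, numeric(1))
  expect_true(all(diff(peaks) > 0))
  # at each drive's peak, that electrode dominates the total
  tot <- Reduce(`+`, drives)
  for (i in seq_along(drives)) {
    k <- peaks[i]
    expect_gt(drives[[i]][k] / tot[k], 0.8)
  }
  # with the slow default memory (tau2 = 150 ms) drives overlap by design:
  # percepts outlast each 50 ms stimulation burst
  dSlow <- simulateTemporal(tr, temporalParams())$r2
  expect_gt(dSlow$time_ms[which.max(dSlow$value)], 100)
})
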
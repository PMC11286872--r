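test_that("fast leaky integration matches the closed form for constant input", {
  wf <- data.frame(time_ms = seq(0, 3, 0.001), value = 1)
  r1 <- integrateStage1(wf, tau1 = 0.3)
  # R1(0.3 ms) = tau1 * (1 - e^-1)
  expect_equal(r1$value[r1$time_ms == 0.3], 0.3 * (1 - exp(-1)),
               tolerance = 1e-6)
  # asymptote A * tau1
  expect_equal(r1$value[nrow(r1)], 0.3, tolerance = 1e-3)
  # zero input -> identically zero
  wf0 <- data.frame(time_ms = seq(0, 1, 0.001), value = 0)
  expect_equal(integrateStage1(wf0, 0.3)$value, rep(0, nrow(wf0)))
  # independent fine-step Euler cross-check
  dtE <- 1e-5
  tE <- seq(0, 0.3, dtE); r <- 0
  for (i in seq_len(length(tE) - 1)) r <- r + dtE * (1 - r / 0.3)
  expect_equal(r1$value[r1$time_ms == 0.3], r, tolerance = 1e-3)
})

test_that("stage-1 numerics agree with the per-phase analytic recursion", {
  set.seed(42)
  for (i in 1:20) {
    tr <- pulseTrain(runif(1, 0.5, 10), runif(1, 0.15, 1),
                     sample(c(25, 50, 100, 200), 1), runif(1, 0.02, 0.08),
                     polarity = sample(c("cathodic-first", "anodic-first"), 1))
    expect_lt(stage1OracleError(tr), 1e-3)
  }
})

test_that("spike strengths are read at positive-phase offsets and rectified", {
  # single cathodic-first pulse: strength = tau1 * (1 - e^(-pw/tau1))^2
  tr <- pulseTrain(1, 0.25, 50, 0.02)
  ev <- extractSpikeStrengths(integrateStage1(sampleWaveform(tr), 0.3), tr)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$time_ms, 0.5)
  expect_equal(ev$strength, 0.3 * (1 - exp(-0.25 / 0.3))^2,
               tolerance = 1e-3)
  # anodic-first: event at the offset of the FIRST phase
  trA <- pulseTrain(1, 0.25, 50, 0.02, polarity = "anodic-first")
  evA <- extractSpikeStrengths(integrateStage1(sampleWaveform(trA), 0.3), trA)
  expect_equal(evA$time_ms, 0.25)
  expect_true(all(evA$strength >= 0))
  # zero amplitude -> all strengths zero
  tr0 <- pulseTrain(0, 0.25, 50, 0.1)
  ev0 <- extractSpikeStrengths(integrateStage1(sampleWaveform(tr0), 0.3), tr0)
  expect_equal(ev0$strength, rep(0, 5))
})

test_that("refractory factor matches the worked example and its limits", {
  expect_equal(round(refractoryFactor(1 / 50), 4), 0.6501)
  expect_equal(refractoryFactor(Inf), 1)
  expect_equal(refractoryFactor(0), 1 - exp(-0.05), tolerance = 1e-12)
  # strictly increasing, bounded in (0, 1]
  d <- seq(0, 0.2, 0.001)
  f <- refractoryFactor(d)
  expect_true(all(diff(f) > 0))
  expect_true(all(f > 0 & f <= 1))
})

test_that("refractory attenuation applies per interval; first event exempt", {
  ev <- data.frame(time_ms = c(0, 20, 40), strength = c(1, 1, 1))
  out <- applyRefractory(ev)
  expect_equal(out$strength[1], 1)
  expect_equal(out$strength[2], refractoryFactor(0.02))
  expect_equal(out$interval_s, c(Inf, 0.02, 0.02))
  expect_true(attr(out, "attenuated"))
})

test_that("gamma kernel is a unit-mass density peaking at (n-1)*tau2", {
  tt <- seq(0, 20 * 3 * 150, 0.5)
  g <- gammaKernel(tt, 150, 3)
  expect_equal(sum(g) * 0.5, 1, tolerance = 1e-3)
  expect_equal(tt[which.max(g)], 2 * 150, tolerance = 1)
  expect_equal(gammaKernel(-5), 0)
  # single impulse through the slow stage peaks at the kernel mode
  ev <- data.frame(time_ms = 0, strength = 2)
  r2 <- slowIntegrate(ev, 150, 3, dt = 1)
  expect_equal(r2$time_ms[which.max(r2$value)], 300, tolerance = 2)
  # linearity: doubling strengths doubles the output
  r2b <- slowIntegrate(transform(ev, strength = strength * 2), 150, 3, dt = 1)
  expect_equal(r2b$value, 2 * r2$value)
})

test_that("compression is bounded, monotone and linear for small input", {
  p <- temporalParams()
  expect_equal(compressResponse(0, p), 0)
  expect_equal(compressResponse(1e9, p), p@sOut, tolerance = 1e-6)
  x <- seq(0, 100, 0.5)
  expect_true(all(diff(compressResponse(x, p)) > 0))
  expect_equal(compressResponse(1e-4, p) / 1e-4, p@sOut * p@sIn / p@pDiv,
               tolerance = 1e-4)
})

test_that("full cascade is amplitude-homogeneous before compression", {
  p <- temporalParams()
  tmpl <- function(a) pulseTrain(a, 0.25, 50, 0.2)
  expect_equal(simulateTemporal(tmpl(0), p)$maxBrightness, 0)
  m1 <- simulateTemporal(tmpl(1), p)$maxR2
  for (c in c(0.5, 2, 7.3))
    expect_equal(simulateTemporal(tmpl(c), p)$maxR2, c * m1,
                 tolerance = 1e-9)
  # monotone in amplitude over a scan
  amps <- seq(0, 10, 1)
  m <- vapply(amps, function(a) simulateTemporal(tmpl(a), p)$maxR2,
              numeric(1))
  expect_true(all(diff(m) >= 0))
})

test_that("the illustration train's brightness rises then decays after offset", {
  p <- temporalParams()
  res <- simulateTemporal(pulseTrain(20, 2, 75, 0.05, dt = 0.02), p)
  b <- res$brightness
  iPeak <- which.max(b$value)
  expect_gt(b$time_ms[iPeak], 50)        # peak after train offset (slow stage)
  expect_gt(b$value[iPeak], b$value[2])  # rises
  expect_lt(b$value[nrow(b)], 0.05 * b$value[iPeak])  # decays away
})

test_that("strength-duration behavior: amplitude threshold falls with pw, charge threshold bottoms out near 0.4 ms", {
  sd <- runStrengthDuration(calParams, pwGrid = c(0.1, 0.2, 0.4, 0.8, 1.6),
                            tol = 1e-4)
  expect_true(all(diff(sd$threshold_uA) < 0))
  # charge threshold is minimized near pw* = 1.256 * tau1 ~ 0.38 ms
  expect_equal(sd$pw_ms[which.min(sd$charge_uAms)], 0.4)
  # amplitude savings per frequency doubling shrink at high rates
  sf <- runStrengthDuration(calParams, fGrid = c(16, 32, 64, 128, 256),
                            tol = 1e-4)
  expect_true(all(diff(sf$threshold_uA) < 0))
  savings <- -diff(log(sf$threshold_uA))
  expect_true(all(diff(savings) < 0))
  # beyond 64 Hz the threshold drops by well under half per doubling
  expect_lt(savings[3], log(2) * 0.5)
})
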
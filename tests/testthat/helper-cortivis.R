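# Shared fixtures and independent oracles for the test suite.

# calibrated defaults, computed once per test file
calParams <- calibrateThetaThresh()

# Analytic per-phase solution of dR/dt = p(t) - R/tau for piecewise-constant
# input: independent oracle for the fast integration stage. `breaks` are the
# segment boundaries (ms), `levels` the input on each segment; returns R at
# the segment boundaries.
r1PiecewiseOracle <- function(breaks, levels, tau) {
  stopifnot(length(breaks) == length(levels) + 1)
  r <- numeric(length(breaks))
  for (k in seq_along(levels)) {
    dt <- breaks[k + 1] - breaks[k]
    r[k + 1] <- r[k] * exp(-dt / tau) + levels[k] * tau * (1 - exp(-dt / tau))
  }
  r
}

# Evaluate the piecewise-constant oracle at arbitrary times
r1OracleAt <- function(breaks, levels, tau, tEval) {
  rAtBreaks <- r1PiecewiseOracle(breaks, levels, tau)
  vapply(tEval, function(t) {
    k <- findInterval(t, breaks, rightmost.closed = TRUE)
    k <- min(max(k, 1), length(levels))
    dt <- t - breaks[k]
    rAtBreaks[k] * exp(-dt / tau) + levels[k] * tau * (1 - exp(-dt / tau))
  }, numeric(1))
}

# Worst relative deviation between the package's fast-stage integration and
# the analytic per-phase recursion over the same piecewise-constant input,
# evaluated at every segment boundary
stage1OracleError <- function(train, tau = 0.3) {
  wf <- sampleWaveform(train)
  r1 <- integrateStage1(wf, tau)
  dt <- wf$time_ms[2] - wf$time_ms[1]
  if (all(wf$value == 0)) return(0)
  # the input is held over each of the n-1 inter-sample intervals
  seg <- rle(wf$value[-nrow(wf)])
  breaks <- c(0, cumsum(seg$lengths)) * dt
  idx <- cumsum(seg$lengths) + 1          # grid index at each segment end
  num <- r1$value[idx]
  ana <- r1PiecewiseOracle(breaks, seg$values, tau)[-1]
  max(abs(num - ana)) / max(abs(ana))
}

# small cortical patch centered on a given eccentricity (memoized per file)
.sheetCache <- new.env()
testSheet <- function(ecc = 3, half = 1.8, spacing = 0.1, seed = 11) {
  key <- paste(ecc, half, spacing, seed, sep = "_")
  if (is.null(.sheetCache[[key]])) {
    x0 <- 15 * log(ecc + 0.5)
    .sheetCache[[key]] <- makeCorticalSheet(
      c(x0 - half, x0 + half), c(-half, half), spacing = spacing, seed = seed)
  }
  .sheetCache[[key]]
}

eccCortexX <- function(ecc, map = retinoMap()) map@k * log(ecc + map@a)
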
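#' The standard calibration pulse train
#'
#' A 50 Hz cathodic-first train with 0.25 ms pulse width and 0.5 s duration:
#' the stimulus that defines the standard electrode (3 uA threshold).
#'
#' @param amplitude current (uA)
#' @param dt sampling step (ms)
#' @return a [PulseTrain-class]
#' @export
standardTrain <- function(amplitude = 3, dt = 0.01) {
  pulseTrain(amplitude, pulseWidth = 0.25, frequency = 50,
             trainDuration = 0.5, polarity = "cathodic-first", dt = dt)
}

#' Calibrate the neural detection threshold
#'
#' The detection threshold `thetaThresh` is defined as the maximum
#' (over time) sensitivity-scaled pre-compression response of a 'standard'
#' electrode — one with a 3 uA threshold for the 50 Hz / 0.25 ms / 0.5 s
#' cathodic-first train — simulated with the calibration sensitivity
#' `sCal = 0.43`. By construction, a threshold search on the standard
#' electrode with the standard train then returns 3 uA.
#'
#' @param params a [TemporalParams-class]
#' @param sCal calibration sensitivity
#' @param amplitude standard-electrode threshold current (uA)
#' @return `params` with `thetaThresh` set
#' @export
calibrateThetaThresh <- function(params = temporalParams(), sCal = 0.43,
                                 amplitude = 3) {
  res <- simulateTemporal(standardTrain(amplitude), params)
  params@thetaThresh <- sCal * res$maxR2
  validObject(params)
  params
}

#' Pre-compression detection response to a pulse train
#'
#' `s * max_t R2(t)`, the quantity compared against `thetaThresh`. Detection
#' is evaluated pre-compression; near threshold the compressive nonlinearity
#' is in its linear range, so the two formulations coincide there.
#' @noRd
.detectionResponse <- function(train, params, s) {
  s * simulateTemporal(train, params)$maxR2
}

#' Find the detection-threshold amplitude for a pulse train
#'
#' Bisection on stimulus amplitude (the pre-compression response is
#' monotone — in fact linear — in amplitude) until the amplitude at which
#' the maximum response over time (and over space, when a sheet and
#' electrode are supplied) reaches `thetaThresh`. Bracketing is verified:
#' the response is below threshold at 0.99x and above at 1.01x the reported
#' value (for tolerances below 1%, at 1 -/+ tol).
#'
#' @param train a [PulseTrain-class] template (its amplitude slot is
#'   ignored)
#' @param params a calibrated [TemporalParams-class]
#' @param s sensitivity scale (defaults to the electrode's `s` when an
#'   electrode is given, else `params@sIn`)
#' @param electrode,sheet optional: threshold on the spatial percept peak of
#'   this electrode on this sheet instead of the temporal response alone
#' @param maxAmp search ceiling (uA; default 10 mA, a typical device safety
#'   ceiling)
#' @param tol relative tolerance of the bisection
#' @return one-row `data.frame(electrode, pw_ms, freq_hz, dur_s,
#'   threshold_uA, tol, s, bracketOk)`; `threshold_uA` is `NA` (not-found
#'   sentinel) when even `maxAmp` stays below threshold
#' @export
findThreshold <- function(train, params, s = NULL, electrode = NULL,
                          sheet = NULL, maxAmp = 1e4, tol = 0.01) {
  if (is.na(params@thetaThresh))
    stop("params must be calibrated first (see calibrateThetaThresh)")
  if (is.null(s)) s <- if (!is.null(electrode)) electrode@s else params@sIn
  spatial <- !is.null(electrode) && !is.null(sheet)
  spatialGain <- if (spatial) {
    sp <- renderSpatialField(sheet, currentField(electrode, sheet, 1))
    max(sp$field)
  } else 1
  respAt <- function(A) {
    tr <- pulseTrain(A, train@pulseWidth, train@frequency,
                     train@trainDuration, train@polarity,
                     train@interphaseGap, train@dt)
    .detectionResponse(tr, params, s) * spatialGain
  }
  id <- if (!is.null(electrode)) electrode@id else NA_character_
  row <- function(thr, ok) data.frame(
    electrode = id, pw_ms = train@pulseWidth, freq_hz = train@frequency,
    dur_s = train@trainDuration, threshold_uA = thr, tol = tol, s = s,
    bracketOk = ok)
  theta <- params@thetaThresh
  if (respAt(maxAmp) < theta) return(row(NA_real_, NA))
  lo <- 0; hi <- maxAmp
  while ((hi - lo) > tol * max(hi, 1e-12) / (1 + tol)) {
    mid <- (lo + hi) / 2
    if (respAt(mid) >= theta) hi <- mid else lo <- mid
  }
  thr <- (lo + hi) / 2
  eps <- max(tol, 0.01)
  ok <- respAt(thr * (1 - eps)) < theta && respAt(thr * (1 + eps)) >= theta
  row(thr, ok)
}

#' Fit per-electrode sensitivity from measured thresholds
#'
#' Model thresholds scale as 1/s, so for each electrode the measured
#' thresholds are regressed on the s = 1 model predictions by least squares
#' through the origin (`measured ~ beta * predicted`, `s = 1/beta`);
#' a log-space option (`s = exp(mean(log predicted - log measured))`) is
#' available. Electrodes sharing rows are fit jointly per electrode id.
#'
#' @param thresholds `data.frame` with columns `electrode`, `pw_ms`,
#'   `freq_hz`, `dur_s`, `threshold_uA` (one row per measured condition)
#' @param params a calibrated [TemporalParams-class]
#' @param space "linear" (default) or "log"
#' @return `data.frame(electrode, s, nObs, rmse)` where `rmse` is the
#'   root-mean-square relative residual of the refit
#' @export
fitSensitivity <- function(thresholds, params, space = c("linear", "log")) {
  space <- match.arg(space)
  stopifnot(all(c("electrode", "pw_ms", "freq_hz", "dur_s", "threshold_uA")
                %in% names(thresholds)))
  if (any(thresholds$threshold_uA <= 0))
    stop("thresholds must be positive")
  if (is.na(params@thetaThresh))
    stop("params must be calibrated first (see calibrateThetaThresh)")
  key <- paste(thresholds$pw_ms, thresholds$freq_hz, thresholds$dur_s)
  uniq <- !duplicated(key)
  predUnit <- vapply(which(uniq), function(i) {
    tr <- pulseTrain(1, thresholds$pw_ms[i], thresholds$freq_hz[i],
                     thresholds$dur_s[i])
    params@thetaThresh / simulateTemporal(tr, params)$maxR2
  }, numeric(1))
  pred <- predUnit[match(key, key[uniq])]
  out <- lapply(split(seq_len(nrow(thresholds)), thresholds$electrode),
                function(ix) {
    tm <- thresholds$threshold_uA[ix]; tp <- pred[ix]
    sHat <- if (space == "linear") sum(tp^2) / sum(tp * tm)
            else exp(mean(log(tp) - log(tm)))
    data.frame(electrode = thresholds$electrode[ix[1]], s = sHat,
               nObs = length(ix),
               rmse = sqrt(mean((tp / sHat - tm)^2 / tm^2)))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Predicted brightness rating for a pulse train
#'
#' Maximum over time of the compressed response
#' `sOut * tanh(s * R2 / pDiv)`: linear in the response for dim percepts and
#' never exceeding `sOut` (10, the top of the rating scale).
#'
#' @param train a [PulseTrain-class]
#' @param params a [TemporalParams-class]
#' @param s sensitivity scale (default `params@sIn`)
#' @return brightness rating in `[0, sOut)`
#' @export
predictBrightness <- function(train, params = temporalParams(), s = NULL) {
  if (is.null(s)) s <- params@sIn
  maxR2 <- simulateTemporal(train, params)$maxR2
  params@sOut * tanh(s * maxR2 / params@pDiv)
}

#' Strength-duration and threshold-frequency curves
#'
#' Detection thresholds over a grid of pulse widths (fixed frequency) or
#' frequencies (fixed pulse width). The curve shape is independent of the
#' electrode up to the scalar sensitivity s, so curves from electrodes that
#' differ only in s superimpose after scaling.
#'
#' @param params a calibrated [TemporalParams-class]
#' @param pwGrid pulse widths (ms); used when non-NULL
#' @param fGrid frequencies (Hz); used when `pwGrid` is NULL
#' @param freq fixed frequency for the pulse-width sweep (Hz)
#' @param pw fixed pulse width for the frequency sweep (ms)
#' @param dur train duration (s)
#' @param s sensitivity
#' @param tol bisection tolerance
#' @return `data.frame(pw_ms, freq_hz, dur_s, threshold_uA, charge_uAms, s)`
#' @export
runStrengthDuration <- function(params, pwGrid = NULL, fGrid = NULL,
                                freq = 50, pw = 0.25, dur = 0.5, s = 0.43,
                                tol = 0.01) {
  if (is.null(pwGrid) && is.null(fGrid))
    stop("provide pwGrid or fGrid")
  grid <- if (!is.null(pwGrid)) data.frame(pw_ms = pwGrid, freq_hz = freq)
          else data.frame(pw_ms = pw, freq_hz = fGrid)
  thr <- vapply(seq_len(nrow(grid)), function(i) {
    tmpl <- pulseTrain(1, grid$pw_ms[i], grid$freq_hz[i], dur)
    findThreshold(tmpl, params, s = s, tol = tol)$threshold_uA
  }, numeric(1))
  data.frame(grid, dur_s = dur, threshold_uA = thr,
             charge_uAms = thr * grid$pw_ms, s = s)
}

#' Phosphene-size experiments over eccentricity, electrode radius and
#' amplitude
#'
#' For each (eccentricity, electrode radius) a small cortical patch is
#' generated around the corresponding cortical site, a surface electrode is
#' placed at its center, and the percept is rendered at amplitudes given as
#' multiples of that configuration's own drawing-threshold amplitude (the
#' current at which the peak brightness reaches `thetaDraw`, i.e. the
#' dimmest drawable percept). Detection thresholds sit orders of magnitude
#' lower and are reported alongside. Sizes are quantified both ways:
#' moment-based ellipse of the thresholded drawing and threshold-free
#' Gaussian fit.
#'
#' @param eccs eccentricities (deg)
#' @param radEs electrode radii (mm)
#' @param ampFactors amplitudes as multiples of the drawing-threshold
#'   amplitude (ignored when `amps` is given)
#' @param amps optional absolute amplitudes (uA) applied identically to
#'   every configuration — the appropriate comparison across electrode
#'   radii, where the threshold-free Gaussian size is the robust metric
#' @param params a calibrated [TemporalParams-class]
#' @param s electrode sensitivity
#' @param seed sheet synthesis seed
#' @param map a [RetinoMap-class]
#' @param sheetSpacing cortical grid step (mm)
#' @param train stimulation train template (default the standard train)
#' @param rfPreset receptive-field preset, see [rfSize()]
#' @param kind electrode kind ("surface" or "depth"); depth uses narrow
#'   current spread so the stimulated-cortex radius tracks the electrode
#'   radius, the controlled comparison for radius sweeps
#' @return `data.frame` with one row per (ecc, radE, ampFactor):
#'   thresholds, ellipse metrics, `gaussSigma_deg`
#' @export
runSizeExperiments <- function(eccs, radEs = 0.25, ampFactors = 2,
                               amps = NULL,
                               params = calibrateThetaThresh(), s = 1,
                               seed = 1, map = retinoMap(),
                               sheetSpacing = 0.1,
                               train = standardTrain(),
                               rfPreset = "keliris", kind = "surface") {
  driveMax <- simulateTemporal(
    pulseTrain(1, train@pulseWidth, train@frequency, train@trainDuration,
               train@polarity, train@interphaseGap, train@dt), params)$maxR2
  rows <- list()
  for (ecc in eccs) {
    x0 <- map@k * log(ecc + map@a)
    # one sheet per eccentricity, sized for the largest electrode, so that
    # radius comparisons see the same neurons
    halfW <- max(radEs) + 1.6
    sheet <- makeCorticalSheet(c(x0 - halfW, x0 + halfW), c(-halfW, halfW),
                               spacing = sheetSpacing, map = map,
                               seed = seed, rfPreset = rfPreset)
    for (radE in radEs) {
      el <- electrode("e1", x0, 0, rad = radE, kind = kind, s = s)
      spUnit <- renderSpatialField(sheet, currentField(el, sheet, 1))
      peakUnit <- max(spUnit$field) * driveMax
      thr <- params@thetaThresh / (s * peakUnit)
      ampDraw <- params@pDiv * atanh(params@thetaDraw / params@sOut) /
        (s * peakUnit)
      ampList <- if (is.null(amps)) ampFactors * ampDraw else amps
      for (ai in seq_along(ampList)) {
        amp <- ampList[ai]
        af <- if (is.null(amps)) ampFactors[ai] else NA_real_
        pcomp <- params; pcomp@sIn <- s
        frame <- compressResponse(spUnit$field * amp * driveMax, pcomp)
        ell <- quantifyEllipse(frame, spUnit$xdeg, spUnit$ydeg,
                               thetaDraw = params@thetaDraw)
        gs <- fitGaussianSize(frame, spUnit$xdeg, spUnit$ydeg)
        rows[[length(rows) + 1]] <- cbind(
          data.frame(ecc_deg = ecc, radE_mm = radE, ampFactor = af,
                     amp_uA = amp, drawThreshold_uA = ampDraw,
                     threshold_uA = thr, s = s, seed = seed),
          ell, data.frame(gaussSigma_deg = gs))
      }
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
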
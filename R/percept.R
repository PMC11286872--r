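#' Build the two-subunit receptive field at one sheet location
#'
#' Each V1 cell is modeled as an ON and an OFF subunit: two anisotropic 2D
#' Gaussians (long axis sigmaRf, short axis sigmaRf/4, both oriented at the
#' location's preferred orientation) displaced by +/- deltaOnOff/2 along the
#' short-axis direction. Only the excitatory components are modeled. Each
#' subunit is a unit-mass density (deg^-2); cells with
#' `|deltaOnOff| > sigmaRf/2` have largely non-overlapping subunits and are
#' classified "simple", others "complex".
#'
#' @param sheet a [CorticalSheet-class]
#' @param i,j grid indices into the sheet (row = cortical x, col = y)
#' @param xdeg,ydeg visual-field grid axes (deg) on which to evaluate
#' @return list with matrices `on` and `off` (unit mass), the subunit
#'   `centers`, `class` ("simple"/"complex"), and the location properties
#' @export
buildRf <- function(sheet, i, j, xdeg, ydeg) {
  stopifnot(is(sheet, "CorticalSheet"))
  sigL <- sheet@sigmaRf[i, j]
  sigS <- sigL / 4
  th <- sheet@theta[i, j]
  del <- sheet@deltaOnOff[i, j]
  cx <- sheet@zRe[i, j]; cy <- sheet@zIm[i, j]
  shortDir <- c(-sin(th), cos(th))
  cOn <- c(cx, cy) + del / 2 * shortDir
  cOff <- c(cx, cy) - del / 2 * shortDir
  list(on = .gauss2(xdeg, ydeg, cOn, th, sigL, sigS),
       off = .gauss2(xdeg, ydeg, cOff, th, sigL, sigS),
       centers = rbind(on = cOn, off = cOff),
       class = if (abs(del) > sigL / 2) "simple" else "complex",
       sigmaRf = sigL, theta = th, deltaOnOff = del,
       wOnOff = sheet@wOnOff[i, j], wOd = sheet@wOd[i, j])
}

#' Oriented unit-mass 2D Gaussian density on a grid
#' @noRd
.gauss2 <- function(xdeg, ydeg, center, theta, sigL, sigS) {
  X <- matrix(xdeg - center[1], length(xdeg), length(ydeg))
  Y <- matrix(ydeg - center[2], length(xdeg), length(ydeg), byrow = TRUE)
  u <- X * cos(theta) + Y * sin(theta)    # along long axis
  v <- -X * sin(theta) + Y * cos(theta)   # along short axis
  exp(-0.5 * (u^2 / sigL^2 + v^2 / sigS^2)) / (2 * pi * sigL * sigS)
}

#' Default pixel spacing for a set of receptive-field sizes: resolve the
#' smallest short axis, bounded to keep grids tractable at high eccentricity
#' @noRd
.defaultPixSpacing <- function(sigmaRf) {
  min(max(min(sigmaRf) / 4 / 5, 0.004), 0.15)
}

#' Pre-compression spatial percept field
#'
#' The linear, time-independent spatial factor of the percept: the sum over
#' stimulated cortical locations of
#' `current * (wOnOff * ON - omega * (1 - wOnOff) * OFF) * eyeWeight`,
#' with each location weighted by its grid cell area so the sum approximates
#' a cortical surface integral (grid-refinement invariant). OFF subunits
#' contribute negative (darker-than-background) intensity. The eye weight is
#' `wOd` for the left eye, `1 - wOd` for the right, and their sum (1) for
#' the default binocular blend.
#'
#' @param sheet a [CorticalSheet-class]
#' @param current matrix of per-location stimulation current (uA), same
#'   dimensions as the sheet maps (see [currentField()])
#' @param omega relative weight of OFF-subunit contributions (default 0.8)
#' @param eyeMode "blend", "left" or "right"
#' @param xdeg,ydeg optional visual-field grid axes; computed from the
#'   stimulated receptive fields (padded 4 sigma) when omitted
#' @param pixSpacing optional pixel spacing (deg)
#' @param cutoff locations with current below `cutoff * max(current)` are
#'   skipped
#' @return list with `field` (matrix, pre-compression intensity), `xdeg`,
#'   `ydeg`, `nActive`
#' @export
renderSpatialField <- function(sheet, current, omega = 0.8,
                               eyeMode = c("blend", "left", "right"),
                               xdeg = NULL, ydeg = NULL, pixSpacing = NULL,
                               cutoff = 1e-3) {
  stopifnot(is(sheet, "CorticalSheet"),
            identical(dim(current), dim(sheet@theta)))
  eyeMode <- match.arg(eyeMode)
  mx <- max(current)
  if (mx <= 0) {
    if (is.null(xdeg)) { xdeg <- seq(-1, 1, 0.05); ydeg <- seq(-1, 1, 0.05) }
    return(list(field = matrix(0, length(xdeg), length(ydeg)),
                xdeg = xdeg, ydeg = ydeg, nActive = 0L))
  }
  act <- which(current > cutoff * mx, arr.ind = TRUE)
  sigL <- sheet@sigmaRf[act]
  sigS <- sigL / 4
  del <- sheet@deltaOnOff[act]
  cx <- sheet@zRe[act]; cy <- sheet@zIm[act]
  if (is.null(xdeg)) {
    pad <- 4 * max(sigL) + max(abs(del)) / 2
    if (is.null(pixSpacing)) pixSpacing <- .defaultPixSpacing(sigL)
    xdeg <- seq(min(cx) - pad, max(cx) + pad, by = pixSpacing)
    ydeg <- seq(min(cy) - pad, max(cy) + pad, by = pixSpacing)
  }
  dx <- xdeg[2] - xdeg[1]
  if (dx > min(sigS) / 4)
    stop("visual grid too coarse: spacing must be <= min(sigmaRf/4)/4")
  th <- sheet@theta[act]
  won <- sheet@wOnOff[act]
  wod <- sheet@wOd[act]
  eyeW <- switch(eyeMode, blend = rep(1, length(wod)), left = wod,
                 right = 1 - wod)
  cellArea <- sheet@spacing^2
  field <- matrix(0, length(xdeg), length(ydeg))
  for (kk in seq_len(nrow(act))) {
    shortDir <- c(-sin(th[kk]), cos(th[kk]))
    half <- 4 * sigL[kk] + abs(del[kk]) / 2
    ix <- which(xdeg >= cx[kk] - half & xdeg <= cx[kk] + half)
    iy <- which(ydeg >= cy[kk] - half & ydeg <= cy[kk] + half)
    if (!length(ix) || !length(iy)) next
    cOn <- c(cx[kk], cy[kk]) + del[kk] / 2 * shortDir
    cOff <- c(cx[kk], cy[kk]) - del[kk] / 2 * shortDir
    on <- .gauss2(xdeg[ix], ydeg[iy], cOn, th[kk], sigL[kk], sigS[kk])
    off <- .gauss2(xdeg[ix], ydeg[iy], cOff, th[kk], sigL[kk], sigS[kk])
    w <- current[act[kk, 1], act[kk, 2]] * cellArea * eyeW[kk]
    field[ix, iy] <- field[ix, iy] +
      w * (won[kk] * on - omega * (1 - won[kk]) * off)
  }
  list(field = field, xdeg = xdeg, ydeg = ydeg, nActive = nrow(act))
}

#' Render the spatiotemporal percept for one electrode
#'
#' Every stage before the output nonlinearity is linear, so the
#' pre-compression percept is exactly separable into one spatial field
#' (current-weighted receptive-field sum) and one temporal drive (the slow
#' response of the pulse train per unit amplitude); frames are the
#' compressed product. This restructuring is exact, not an approximation.
#' The electrode's sensitivity `s` takes the place of the compression
#' sensitivity for spatial rendering.
#'
#' @param sheet a [CorticalSheet-class]
#' @param electrode an [Electrode-class] (placed on the sheet)
#' @param train a [PulseTrain-class]; its amplitude sets the injected current
#' @param params a [TemporalParams-class]
#' @param eyeMode "blend", "left" or "right"
#' @param omega OFF-subunit weight
#' @param dtFrame frame step (ms)
#' @param xdeg,ydeg,pixSpacing optional grid control, see
#'   [renderSpatialField()]
#' @return a [PerceptMovie-class]; frames are signed brightness in
#'   `(-sOut, sOut)`
#' @export
renderPercept <- function(sheet, electrode, train, params = temporalParams(),
                          eyeMode = "blend", omega = 0.8, dtFrame = 10,
                          xdeg = NULL, ydeg = NULL, pixSpacing = NULL) {
  stopifnot(is(electrode, "Electrode"))
  cf <- currentField(electrode, sheet, Iinput = train@amplitude)
  sp <- renderSpatialField(sheet, cf, omega = omega, eyeMode = eyeMode,
                           xdeg = xdeg, ydeg = ydeg, pixSpacing = pixSpacing)
  unitTrain <- pulseTrain(1, train@pulseWidth, train@frequency,
                          train@trainDuration, train@polarity,
                          train@interphaseGap, train@dt)
  drive <- simulateTemporal(unitTrain, params)$r2
  ft <- seq(0, max(drive$time_ms), by = dtFrame)
  dv <- stats::approx(drive$time_ms, drive$value, xout = ft)$y
  pcomp <- params; pcomp@sIn <- electrode@s
  frames <- array(0, c(length(sp$xdeg), length(sp$ydeg), length(ft)))
  for (k in seq_along(ft))
    frames[, , k] <- compressResponse(sp$field * dv[k], pcomp)
  new("PerceptMovie", xdeg = sp$xdeg, ydeg = sp$ydeg, frames = frames,
      timesMs = ft,
      meta = list(electrode = electrode@id, s = electrode@s,
                  amplitude = train@amplitude, nActive = sp$nActive,
                  pixSpacing = sp$xdeg[2] - sp$xdeg[1], eyeMode = eyeMode,
                  omega = omega, separable = TRUE))
}

#' Render a multi-electrode stimulation schedule
#'
#' Superposes the pre-compression spatiotemporal drives of several
#' electrodes (each electrode set x pulse train x onset), then compresses.
#' Supports both simultaneous (shared onset) and sequential schedules, e.g.
#' tracing letter shapes 50 ms per electrode with 50 ms delays.
#'
#' @param sheet a [CorticalSheet-class]
#' @param schedule list of entries, each a list with elements `electrode`
#'   (an [Electrode-class]), `train` (a [PulseTrain-class]) and `onsetMs`
#' @param params a [TemporalParams-class]
#' @param eyeMode,omega,dtFrame,pixSpacing see [renderPercept()]
#' @return a [PerceptMovie-class]
#' @export
renderSequence <- function(sheet, schedule, params = temporalParams(),
                           eyeMode = "blend", omega = 0.8, dtFrame = 10,
                           pixSpacing = NULL) {
  stopifnot(length(schedule) >= 1)
  fields <- vector("list", length(schedule))
  drives <- vector("list", length(schedule))
  sVals <- numeric(length(schedule))
  # common visual grid from the union of stimulated receptive fields
  allSig <- c(); xr <- c(); yr <- c()
  cfs <- vector("list", length(schedule))
  for (k in seq_along(schedule)) {
    e <- schedule[[k]]$electrode; tr <- schedule[[k]]$train
    cfs[[k]] <- currentField(e, sheet, Iinput = tr@amplitude)
    act <- which(cfs[[k]] > 1e-3 * max(cfs[[k]]), arr.ind = TRUE)
    allSig <- c(allSig, sheet@sigmaRf[act])
    xr <- range(c(xr, sheet@zRe[act])); yr <- range(c(yr, sheet@zIm[act]))
  }
  pad <- 4 * max(allSig)
  if (is.null(pixSpacing)) pixSpacing <- .defaultPixSpacing(allSig)
  xdeg <- seq(xr[1] - pad, xr[2] + pad, by = pixSpacing)
  ydeg <- seq(yr[1] - pad, yr[2] + pad, by = pixSpacing)
  tEnd <- 0
  for (k in seq_along(schedule)) {
    e <- schedule[[k]]$electrode; tr <- schedule[[k]]$train
    sVals[k] <- e@s
    fields[[k]] <- renderSpatialField(sheet, cfs[[k]], omega = omega,
                                      eyeMode = eyeMode,
                                      xdeg = xdeg, ydeg = ydeg)$field
    unitTrain <- pulseTrain(1, tr@pulseWidth, tr@frequency, tr@trainDuration,
                            tr@polarity, tr@interphaseGap, tr@dt)
    drives[[k]] <- simulateTemporal(unitTrain, params)$r2
    tEnd <- max(tEnd, schedule[[k]]$onsetMs + max(drives[[k]]$time_ms))
  }
  ft <- seq(0, tEnd, by = dtFrame)
  frames <- array(0, c(length(xdeg), length(ydeg), length(ft)))
  for (k in seq_along(schedule)) {
    on <- schedule[[k]]$onsetMs
    dv <- stats::approx(drives[[k]]$time_ms + on, drives[[k]]$value,
                        xout = ft, yleft = 0, yright = 0)$y
    for (i in seq_along(ft))
      if (dv[i] != 0)
        frames[, , i] <- frames[, , i] + sVals[k] * fields[[k]] * dv[i]
  }
  pcomp <- params; pcomp@sIn <- 1  # sensitivity already applied per electrode
  for (i in seq_along(ft))
    frames[, , i] <- compressResponse(frames[, , i], pcomp)
  new("PerceptMovie", xdeg = xdeg, ydeg = ydeg, frames = frames, timesMs = ft,
      meta = list(nElectrodes = length(schedule), eyeMode = eyeMode,
                  omega = omega, pixSpacing = pixSpacing))
}

#' Peak frame of a percept movie
#'
#' The frame at the time of maximum absolute intensity (for a single
#' electrode this is the frame at the peak of the temporal drive).
#'
#' @param movie a [PerceptMovie-class]
#' @return list with `frame` (matrix), `xdeg`, `ydeg`, `timeMs`
#' @export
peakFrame <- function(movie) {
  stopifnot(is(movie, "PerceptMovie"))
  peaks <- apply(abs(movie@frames), 3, max)
  k <- which.max(peaks)
  list(frame = movie@frames[, , k], xdeg = movie@xdeg, ydeg = movie@ydeg,
       timeMs = movie@timesMs[k])
}

setMethod("show", "PerceptMovie", function(object) {
  cat(sprintf(
    "PerceptMovie: %d x %d px (%.2f deg/px), %d frames over %g ms, peak |I| = %.3g\n",
    length(object@xdeg), length(object@ydeg),
    object@xdeg[2] - object@xdeg[1], length(object@timesMs),
    max(object@timesMs), max(abs(object@frames))))
})
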
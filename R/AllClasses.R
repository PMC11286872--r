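#' @import methods
NULL

#' Biphasic pulse-train specification
#'
#' Parametric description of a charge-balanced biphasic pulse train of the
#' kind delivered through cortical stimulating electrodes. Each pulse consists
#' of two equal-magnitude, opposite-sign rectangular phases (optionally
#' separated by an interphase gap); trains are cathodic-first by convention.
#'
#' @slot amplitude current per phase (uA), >= 0
#' @slot pulseWidth duration of each phase (ms)
#' @slot frequency pulse rate (Hz)
#' @slot trainDuration total train duration (s)
#' @slot polarity "cathodic-first" or "anodic-first"
#' @slot interphaseGap gap between the two phases (ms)
#' @slot dt sampling step used when the waveform is discretized (ms)
#' @seealso [pulseTrain()], [sampleWaveform()]
#' @export
setClass("PulseTrain",
  representation(
    amplitude = "numeric",
    pulseWidth = "numeric",
    frequency = "numeric",
    trainDuration = "numeric",
    polarity = "character",
    interphaseGap = "numeric",
    dt = "numeric"
  )
)

setValidity("PulseTrain", function(object) {
  msg <- character()
  if (length(object@amplitude) != 1 || is.na(object@amplitude) || object@amplitude < 0)
    msg <- c(msg, "amplitude must be a single non-negative number (uA)")
  if (object@pulseWidth <= 0) msg <- c(msg, "pulseWidth must be > 0 (ms)")
  if (object@frequency <= 0) msg <- c(msg, "frequency must be > 0 (Hz)")
  if (object@trainDuration <= 0) msg <- c(msg, "trainDuration must be > 0 (s)")
  if (!object@polarity %in% c("cathodic-first", "anodic-first"))
    msg <- c(msg, "polarity must be 'cathodic-first' or 'anodic-first'")
  if (object@interphaseGap < 0) msg <- c(msg, "interphaseGap must be >= 0 (ms)")
  if (object@dt <= 0) msg <- c(msg, "dt must be > 0 (ms)")
  period <- 1000 / object@frequency
  if (2 * object@pulseWidth + object@interphaseGap > period)
    msg <- c(msg, sprintf(
      "pulse period (%.3f ms) too short for two %.3f ms phases plus %.3f ms gap",
      period, object@pulseWidth, object@interphaseGap))
  if (length(msg)) msg else TRUE
})

#' Temporal-cascade parameters
#'
#' Constants of the pulse-train-to-brightness transformation: fast leaky
#' integration of current (tau1), refractory attenuation of spiking strength
#' (tauR, delta), slow n-stage leaky integration (tau2, nCascades), and the
#' compressive output nonlinearity (sIn, pDiv, sOut). thetaThresh is the
#' detection threshold on the (sensitivity-scaled, pre-compression) response;
#' thetaDraw is the drawing threshold on the brightness scale.
#'
#' @slot tau1 fast time constant (ms)
#' @slot tauR refractory rate (1/s)
#' @slot delta refractory offset (s)
#' @slot tau2 slow time constant (ms)
#' @slot nCascades number of cascaded slow stages (integer >= 1)
#' @slot sIn sensitivity scale multiplying the slow response
#' @slot pDiv compression divisor
#' @slot sOut compression asymptote (brightness rating units)
#' @slot thetaThresh detection threshold (response units; NA until calibrated)
#' @slot thetaDraw drawing threshold (rating units)
#' @seealso [temporalParams()], [calibrateThetaThresh()]
#' @export
setClass("TemporalParams",
  representation(
    tau1 = "numeric", tauR = "numeric", delta = "numeric",
    tau2 = "numeric", nCascades = "numeric",
    sIn = "numeric", pDiv = "numeric", sOut = "numeric",
    thetaThresh = "numeric", thetaDraw = "numeric"
  )
)

setValidity("TemporalParams", function(object) {
  msg <- character()
  if (object@tau1 <= 0) msg <- c(msg, "tau1 must be > 0 (ms)")
  if (object@tauR <= 0) msg <- c(msg, "tauR must be > 0 (1/s)")
  if (object@delta < 0) msg <- c(msg, "delta must be >= 0 (s)")
  if (object@tau2 <= 0) msg <- c(msg, "tau2 must be > 0 (ms)")
  if (object@nCascades < 1 || object@nCascades != round(object@nCascades))
    msg <- c(msg, "nCascades must be an integer >= 1")
  if (object@sIn <= 0) msg <- c(msg, "sIn must be > 0")
  if (object@pDiv <= 0) msg <- c(msg, "pDiv must be > 0")
  if (object@sOut <= 0) msg <- c(msg, "sOut must be > 0")
  if (!is.na(object@thetaThresh) && object@thetaThresh <= 0)
    msg <- c(msg, "thetaThresh must be > 0 when set")
  if (object@thetaDraw < 0) msg <- c(msg, "thetaDraw must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Conformal retinotopic map
#'
#' Log-polar (complex logarithm) map between the visual field (degrees, as a
#' complex number z = horizontal + i*vertical eccentricity) and the flattened
#' V1 cortical sheet (mm, complex w): w = k*log(z + a), with the cortical
#' imaginary axis optionally compressed by `squish`.
#'
#' @slot k cortical scale factor (mm)
#' @slot a foveal offset (deg)
#' @slot squish anisotropy factor applied to the cortical y dimension
#' @slot hemisphere "left" (maps the right hemifield) or "right"
#' @seealso [retinoMap()], [visualToCortex()], [cortexToVisual()]
#' @export
setClass("RetinoMap",
  representation(k = "numeric", a = "numeric", squish = "numeric",
                 hemisphere = "character")
)

setValidity("RetinoMap", function(object) {
  msg <- character()
  if (object@k <= 0) msg <- c(msg, "k must be > 0 (mm)")
  if (object@a <= 0) msg <- c(msg, "a must be > 0 (deg)")
  if (object@squish <= 0) msg <- c(msg, "squish must be > 0")
  if (!object@hemisphere %in% c("left", "right"))
    msg <- c(msg, "hemisphere must be 'left' or 'right'")
  if (length(msg)) msg else TRUE
})

#' Gridded flattened-cortex patch
#'
#' A rectangular grid on the flattened cortical surface carrying, at every
#' grid location, the synthesized neuronal properties used for phosphene
#' rendering: preferred orientation, ocular dominance, on/off-subunit balance
#' and separation, receptive-field size, and the retinotopic visual-field
#' position. All property maps share dimension
#' `length(xmm) x length(ymm)` (rows index cortical x).
#'
#' @slot xmm,ymm cortical grid axes (mm)
#' @slot theta preferred orientation (rad, (-pi/2, pi/2])
#' @slot wOd ocular dominance in [0, 1] (1 = left eye)
#' @slot wOnOff on/off balance in [0, 1] (1 = pure ON)
#' @slot deltaOnOff signed on/off subunit separation (deg)
#' @slot sigmaRf receptive-field long axis (deg)
#' @slot zRe,zIm visual-field position of each location (deg)
#' @slot map the generating [RetinoMap-class]
#' @slot spacing grid step (mm)
#' @slot seed RNG seed used for map synthesis
#' @slot params list of synthesis parameters (odPeriod, sigmaF, rfPreset)
#' @seealso [makeCorticalSheet()]
#' @export
setClass("CorticalSheet",
  representation(
    xmm = "numeric", ymm = "numeric",
    theta = "matrix", wOd = "matrix", wOnOff = "matrix",
    deltaOnOff = "matrix", sigmaRf = "matrix",
    zRe = "matrix", zIm = "matrix",
    map = "RetinoMap", spacing = "numeric", seed = "numeric",
    params = "list"
  )
)

setValidity("CorticalSheet", function(object) {
  msg <- character()
  dims <- dim(object@theta)
  if (!identical(dims, c(length(object@xmm), length(object@ymm))))
    msg <- c(msg, "map dimensions must be length(xmm) x length(ymm)")
  for (nm in c("wOd", "wOnOff", "deltaOnOff", "sigmaRf", "zRe", "zIm"))
    if (!identical(dim(slot(object, nm)), dims))
      msg <- c(msg, sprintf("%s must have the same dimensions as theta", nm))
  if (any(object@wOd < 0 | object@wOd > 1)) msg <- c(msg, "wOd must lie in [0, 1]")
  if (any(object@wOnOff < 0 | object@wOnOff > 1)) msg <- c(msg, "wOnOff must lie in [0, 1]")
  if (any(object@sigmaRf <= 0)) msg <- c(msg, "sigmaRf must be > 0 everywhere")
  if (any(!is.finite(object@theta)) || any(!is.finite(object@deltaOnOff)))
    msg <- c(msg, "all property maps must be finite")
  if (length(msg)) msg else TRUE
})

#' Stimulating electrode
#'
#' @slot id electrode identifier
#' @slot x,y cortical position of the electrode center (mm)
#' @slot rad electrode radius (mm)
#' @slot kind "surface" or "depth"
#' @slot K current-spread falloff constant (per mm^2 of distance from the
#'   electrode edge; 675 for surface, 1e5 for depth electrodes)
#' @slot s per-electrode sensitivity scale
#' @seealso [electrode()], [currentField()]
#' @export
setClass("Electrode",
  representation(id = "character", x = "numeric", y = "numeric",
                 rad = "numeric", kind = "character", K = "numeric",
                 s = "numeric")
)

setValidity("Electrode", function(object) {
  msg <- character()
  if (object@rad < 0) msg <- c(msg, "rad must be >= 0 (mm)")
  if (object@K <= 0) msg <- c(msg, "K must be > 0")
  if (object@s <= 0) msg <- c(msg, "s must be > 0")
  if (!object@kind %in% c("surface", "depth"))
    msg <- c(msg, "kind must be 'surface' or 'depth'")
  if (length(msg)) msg else TRUE
})

#' Electrode array
#'
#' @slot electrodes list of [Electrode-class] objects with unique ids
#' @slot layout metadata list (generation rule, pitch, rotation, ...)
#' @seealso [generateArray()], [gridArray()]
#' @export
setClass("ElectrodeArray",
  representation(electrodes = "list", layout = "list")
)

setValidity("ElectrodeArray", function(object) {
  msg <- character()
  if (!all(vapply(object@electrodes, is, logical(1), class2 = "Electrode")))
    msg <- c(msg, "electrodes must all be Electrode objects")
  ids <- vapply(object@electrodes, function(e) e@id, character(1))
  if (anyDuplicated(ids)) msg <- c(msg, "electrode ids must be unique")
  if (length(msg)) msg else TRUE
})

#' Rendered percept movie
#'
#' Frames of predicted phosphene intensity over a visual-field pixel grid.
#' Intensities are on the compressed brightness-rating scale and signed:
#' negative values are regions perceived darker than the background
#' (OFF-subunit driven).
#'
#' @slot xdeg,ydeg visual-field pixel axes (deg)
#' @slot frames array `[length(xdeg), length(ydeg), length(timesMs)]`
#' @slot timesMs frame times (ms)
#' @slot meta metadata list (params, electrodes, grid spacing, ...)
#' @seealso [renderPercept()], [peakFrame()], [quantifyEllipse()]
#' @export
setClass("PerceptMovie",
  representation(xdeg = "numeric", ydeg = "numeric", frames = "array",
                 timesMs = "numeric", meta = "list")
)

setValidity("PerceptMovie", function(object) {
  msg <- character()
  d <- dim(object@frames)
  if (length(d) != 3 ||
      !identical(d, c(length(object@xdeg), length(object@ydeg), length(object@timesMs))))
    msg <- c(msg, "frames must be an [x, y, t] array matching the grid and times")
  if (length(msg)) msg else TRUE
})
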
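#' Construct a biphasic pulse-train specification
#'
#' @param amplitude current per phase (uA)
#' @param pulseWidth phase duration (ms)
#' @param frequency pulse rate (Hz)
#' @param trainDuration train duration (s)
#' @param polarity "cathodic-first" (default) or "anodic-first"
#' @param interphaseGap gap between the two phases (ms, default 0)
#' @param dt sampling step for waveform discretization (ms). Defaults to
#'   0.01 ms, fine enough to resolve both the pulse phases and the fast
#'   integration time constant.
#' @return a [PulseTrain-class] object
#' @examples
#' pt <- pulseTrain(amplitude = 3, pulseWidth = 0.25, frequency = 50,
#'                  trainDuration = 0.5)
#' nPulses(pt)
#' @export
pulseTrain <- function(amplitude, pulseWidth, frequency, trainDuration,
                       polarity = "cathodic-first", interphaseGap = 0,
                       dt = 0.01) {
  new("PulseTrain", amplitude = as.numeric(amplitude),
      pulseWidth = as.numeric(pulseWidth), frequency = as.numeric(frequency),
      trainDuration = as.numeric(trainDuration), polarity = polarity,
      interphaseGap = as.numeric(interphaseGap), dt = as.numeric(dt))
}

#' Number of complete pulses in a train
#'
#' @param train a [PulseTrain-class]
#' @return integer count, `floor(trainDuration * frequency)`
#' @export
nPulses <- function(train) {
  stopifnot(is(train, "PulseTrain"))
  as.integer(floor(train@trainDuration * train@frequency + 1e-9))
}

#' Onset times of each pulse (ms)
#' @noRd
pulseOnsets <- function(train) {
  (seq_len(nPulses(train)) - 1) * 1000 / train@frequency
}

#' Times at which spiking is read out: the offset of the positive phase
#' of each biphasic pulse (ms). For cathodic-first pulses the positive
#' phase is the second; for anodic-first, the first.
#' @noRd
positivePhaseOffsets <- function(train) {
  on <- pulseOnsets(train)
  if (train@polarity == "cathodic-first") {
    on + 2 * train@pulseWidth + train@interphaseGap
  } else {
    on + train@pulseWidth
  }
}

#' Sample the current waveform of a pulse train
#'
#' Discretizes the biphasic train on a regular time grid. Sampling is
#' piecewise-constant on phase boundaries: each sample takes the phase value
#' of the interval it starts in, and phase boundaries are aligned to the grid
#' by requiring `dt` to resolve the pulse width (guard: `dt <=
#' pulseWidth / 10`). The sampled waveform is charge balanced to within one
#' sample.
#'
#' @param train a [PulseTrain-class]
#' @return a response trace: `data.frame(time_ms, value)` with current in uA.
#'   Time starts at 0 and extends one slow-integration tail beyond the train
#'   (attribute `"trainDuration_ms"` records the nominal train end).
#' @export
sampleWaveform <- function(train) {
  stopifnot(is(train, "PulseTrain"))
  dt <- train@dt
  if (dt > train@pulseWidth / 10 + 1e-12)
    stop("dt must be <= pulseWidth/10 to resolve the pulse phases")
  durMs <- train@trainDuration * 1000
  time <- seq(0, durMs, by = dt)
  value <- numeric(length(time))
  sgn1 <- if (train@polarity == "cathodic-first") -1 else 1
  nPw <- round(train@pulseWidth / dt)
  nGap <- round(train@interphaseGap / dt)
  n <- length(value)
  # Index-aligned phases: each phase occupies exactly nPw samples, so the
  # sampled waveform is charge balanced by construction (onsets not on the
  # grid are shifted by at most dt/2).
  for (on in pulseOnsets(train)) {
    i0 <- round(on / dt) + 1L
    i1 <- i0 + seq_len(nPw) - 1L
    i2 <- i0 + nPw + nGap + seq_len(nPw) - 1L
    value[i1[i1 <= n]] <- sgn1 * train@amplitude
    value[i2[i2 <= n]] <- -sgn1 * train@amplitude
  }
  out <- data.frame(time_ms = time, value = value)
  attr(out, "trainDuration_ms") <- durMs
  out
}

setMethod("show", "PulseTrain", function(object) {
  cat(sprintf(
    "PulseTrain: %s, %g uA, pw %g ms, %g Hz, %g s (%d pulses), gap %g ms, dt %g ms\n",
    object@polarity, object@amplitude, object@pulseWidth, object@frequency,
    object@trainDuration, nPulses(object), object@interphaseGap, object@dt))
})
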
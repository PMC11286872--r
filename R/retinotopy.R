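#' Construct a conformal retinotopic map
#'
#' The flattened-V1 template maps a visual-field point z (deg, complex:
#' real = horizontal, imaginary = vertical eccentricity) to a cortical point
#' w (mm) via the complex logarithm `w = k * log(z + a)`; the cortical
#' imaginary axis is additionally scaled by `squish`. Standard parameters are
#' a = 0.5 deg, k = 15 mm, squish = 1.
#'
#' @param k cortical scale (mm)
#' @param a foveal offset (deg)
#' @param squish cortical-y anisotropy factor
#' @param hemisphere "left" (represents the right visual hemifield, default)
#'   or "right"
#' @return a [RetinoMap-class]
#' @seealso [retinoPreset()]
#' @export
retinoMap <- function(k = 15, a = 0.5, squish = 1, hemisphere = "left") {
  new("RetinoMap", k = k, a = a, squish = squish, hemisphere = hemisphere)
}

#' Named retinotopic-map presets
#'
#' `"standard"` is the template map (a = 0.5, k = 15, squish = 1).
#' `"beauchamp2020"` is the parameter set that best located the 24 phosphenes
#' of a published 4 x 6 surface-grid implant (a = 0.15, k = 16.6,
#' squish = 0.63); it ships as a constant, not re-fit.
#'
#' @param name preset name
#' @param hemisphere passed to [retinoMap()]
#' @return a [RetinoMap-class]
#' @export
retinoPreset <- function(name = c("standard", "beauchamp2020"),
                         hemisphere = "left") {
  name <- match.arg(name)
  switch(name,
    standard = retinoMap(15, 0.5, 1, hemisphere),
    beauchamp2020 = retinoMap(16.6, 0.15, 0.63, hemisphere))
}

setMethod("show", "RetinoMap", function(object) {
  cat(sprintf("RetinoMap (%s hemisphere): k = %g mm, a = %g deg, squish = %g\n",
              object@hemisphere, object@k, object@a, object@squish))
})

#' Map visual-field points onto the cortical sheet
#'
#' `w = k * log(z + a)` (principal branch), then `Im(w)` is multiplied by
#' `squish`. For a right-hemisphere map the left hemifield is mirrored
#' (`Re(z)` negated) before mapping so both sheets use the same coordinates.
#'
#' @param z visual-field points (complex, deg); the mapped hemifield requires
#'   `Re(z) >= 0` after hemisphere reflection
#' @param map a [RetinoMap-class]
#' @return cortical points (complex, mm)
#' @examples
#' visualToCortex(1 + 0i, retinoMap())   # 15*log(1.5) = 6.08 mm
#' @export
visualToCortex <- function(z, map = retinoMap()) {
  stopifnot(is(map, "RetinoMap"))
  z <- as.complex(z)
  if (map@hemisphere == "right") z <- complex(real = -Re(z), imaginary = Im(z))
  if (any(Re(z) < -1e-9))
    stop("z outside the mapped hemifield (Re(z) < 0 after reflection)")
  if (any(Mod(z + map@a) < 1e-12))
    stop("z = -a is the singularity of the log map")
  w <- map@k * log(z + map@a)
  complex(real = Re(w), imaginary = Im(w) * map@squish)
}

#' Map cortical points back to the visual field
#'
#' Exact inverse of [visualToCortex()]: un-squish the imaginary part, then
#' `z = exp(w/k) - a` (and un-mirror for right-hemisphere maps).
#'
#' @param w cortical points (complex, mm)
#' @param map a [RetinoMap-class]
#' @return visual-field points (complex, deg)
#' @export
cortexToVisual <- function(w, map = retinoMap()) {
  stopifnot(is(map, "RetinoMap"))
  w <- as.complex(w)
  w <- complex(real = Re(w), imaginary = Im(w) / map@squish)
  z <- exp(w / map@k) - map@a
  if (map@hemisphere == "right") z <- complex(real = -Re(z), imaginary = Im(z))
  z
}

#' Cortical magnification along the horizontal meridian
#'
#' `M(ecc) = k / (ecc + a)` mm of cortex per degree of visual field,
#' the modulus of the map derivative on the horizontal meridian.
#'
#' @param ecc eccentricity (deg, >= 0)
#' @param map a [RetinoMap-class]
#' @return magnification (mm/deg)
#' @examples
#' corticalMagnification(0)    # 30 mm/deg at the fovea
#' @export
corticalMagnification <- function(ecc, map = retinoMap()) {
  stopifnot(all(ecc >= 0))
  map@k / (ecc + map@a)
}
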
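#' Construct a stimulating electrode
#'
#' @param id identifier
#' @param x,y cortical position of the center (mm)
#' @param rad electrode radius (mm)
#' @param kind "surface" or "depth"; depth electrodes are modeled as surface
#'   points with extremely narrow current spread
#' @param K current falloff constant; defaults to 675 for surface and 1e5
#'   for depth electrodes. K carries units uA/mm^2 in the literature but
#'   functions as 1/mm^2 in the spread formula with distances in mm; it is
#'   stored as a bare number.
#' @param s per-electrode sensitivity scale
#' @return an [Electrode-class]
#' @export
electrode <- function(id, x, y, rad = 0.25, kind = c("surface", "depth"),
                      K = NULL, s = 1) {
  kind <- match.arg(kind)
  if (is.null(K)) K <- if (kind == "surface") 675 else 1e5
  new("Electrode", id = as.character(id), x = x, y = y, rad = rad,
      kind = kind, K = K, s = s)
}

setMethod("show", "Electrode", function(object) {
  cat(sprintf("Electrode '%s' (%s): center (%.2f, %.2f) mm, rad %g mm, K %g, s %g\n",
              object@id, object@kind, object@x, object@y, object@rad,
              object@K, object@s))
})

#' Construct an electrode array
#'
#' @param electrodes list of [Electrode-class] objects
#' @param layout metadata list
#' @return an [ElectrodeArray-class]
#' @export
electrodeArray <- function(electrodes, layout = list()) {
  new("ElectrodeArray", electrodes = electrodes, layout = layout)
}

setMethod("show", "ElectrodeArray", function(object) {
  cat(sprintf("ElectrodeArray: %d electrodes (rule: %s)\n",
              length(object@electrodes),
              if (is.null(object@layout$rule)) "custom" else object@layout$rule))
})

#' @describeIn electrodeArray number of electrodes
#' @param x an [ElectrodeArray-class]
#' @export
setMethod("length", "ElectrodeArray", function(x) length(x@electrodes))

#' Cortical positions of an array as a data.frame
#'
#' @param array an [ElectrodeArray-class]
#' @return `data.frame(id, x_mm, y_mm, rad_mm, kind, s)`
#' @export
arrayPositions <- function(array) {
  stopifnot(is(array, "ElectrodeArray"))
  do.call(rbind, lapply(array@electrodes, function(e)
    data.frame(id = e@id, x_mm = e@x, y_mm = e@y, rad_mm = e@rad,
               kind = e@kind, s = e@s)))
}

#' Current at a cortical distance from an electrode
#'
#' Current-distance relation with a plateau over the electrode footprint:
#' `I = Iinput` for `rad <= radE`, and
#' `I = Iinput / (1 + K * (rad - radE)^2)` beyond it. Continuous and
#' non-increasing in distance, and proportional to the injected current.
#'
#' @param rad radial distance from the electrode center (mm)
#' @param Iinput injected current (uA)
#' @param radE electrode radius (mm)
#' @param K falloff constant (675 surface default; 1e5 for depth)
#' @return current (uA), same length as `rad`
#' @examples
#' currentAt(1.25, 100, 0.25)   # 100/676 at 1 mm beyond the edge
#' @export
currentAt <- function(rad, Iinput, radE = 0.25, K = 675) {
  stopifnot(all(rad >= 0), radE >= 0, K > 0)
  d <- pmax(rad - radE, 0)
  Iinput / (1 + K * d^2)
}

#' Current delivered to every sheet location by an electrode
#'
#' Evaluates [currentAt()] over the sheet grid, with distance measured to
#' the nearest point of the circular electrode footprint.
#'
#' @param electrode an [Electrode-class]
#' @param sheet a [CorticalSheet-class]
#' @param Iinput injected current (uA)
#' @return matrix (uA) with the sheet's map dimensions
#' @export
currentField <- function(electrode, sheet, Iinput = 1) {
  stopifnot(is(electrode, "Electrode"), is(sheet, "CorticalSheet"))
  if (electrode@x < min(sheet@xmm) || electrode@x > max(sheet@xmm) ||
      electrode@y < min(sheet@ymm) || electrode@y > max(sheet@ymm))
    stop(sprintf("electrode '%s' lies outside the sheet extent", electrode@id))
  dist <- sqrt(outer((sheet@xmm - electrode@x)^2,
                     (sheet@ymm - electrode@y)^2, "+"))
  matrix(currentAt(as.vector(dist), Iinput, electrode@rad, electrode@K),
         nrow = length(sheet@xmm))
}

#' Optimal electrode spacing on the cortical surface
#'
#' First-order spacing rule `rho(x) = (m*x + b) * k / (x + a)`: phosphene
#' size in visual degrees (linear in eccentricity, slope m, intercept b)
#' times cortical magnification. Electrodes closer together than `rho`
#' produce overlapping phosphenes. With the default constants the spacing is
#' `k*b/a` = 4.8 mm at the fovea and asymptotes to `k*m` = 1.2 mm in the far
#' periphery, i.e. optimal arrays pack electrodes LESS densely toward the
#' foveal representation.
#'
#' @param ecc eccentricity (deg, >= 0)
#' @param m,b phosphene-size slope (deg/deg) and intercept (deg)
#' @param map a [RetinoMap-class] supplying k and a
#' @return spacing (mm)
#' @examples
#' optimalSpacing(20)   # 1.29 mm, prints as 1.3
#' @export
optimalSpacing <- function(ecc, m = 0.08, b = 0.16, map = retinoMap()) {
  stopifnot(all(ecc >= 0), m > 0, b > 0)
  (m * ecc + b) * map@k / (ecc + map@a)
}

#' Exact (non-Taylor) optimal spacing from the map itself
#'
#' `y(x + sigma/2) - y(x - sigma/2)` with `y = k*log(x + a)`; reference
#' for the first-order rule.
#' @inheritParams optimalSpacing
#' @return spacing (mm)
#' @export
optimalSpacingExact <- function(ecc, m = 0.08, b = 0.16, map = retinoMap()) {
  sig <- m * ecc + b
  map@k * (log(ecc + sig / 2 + map@a) - log(pmax(ecc - sig / 2, 0) + map@a))
}

#' Rectangular electrode grid on the cortical surface
#'
#' Regular `nrow x ncol` grid with fixed pitch, optionally rotated, e.g. the
#' 4 x 6 surface-grid configuration with 2 mm separation used in published
#' letter-tracing experiments.
#'
#' @param nrow,ncol grid dimensions
#' @param pitch center-to-center separation (mm)
#' @param center cortical center of the grid (mm, length 2)
#' @param angle rotation (rad)
#' @param rad electrode radius (mm)
#' @param kind,s passed to [electrode()]
#' @return an [ElectrodeArray-class]
#' @export
gridArray <- function(nrow = 4, ncol = 6, pitch = 2, center = c(0, 0),
                      angle = 0, rad = 0.25, kind = "surface", s = 1) {
  xs <- (seq_len(ncol) - (ncol + 1) / 2) * pitch
  ys <- (seq_len(nrow) - (nrow + 1) / 2) * pitch
  g <- expand.grid(x = xs, y = ys)
  xr <- center[1] + g$x * cos(angle) - g$y * sin(angle)
  yr <- center[2] + g$x * sin(angle) + g$y * cos(angle)
  els <- mapply(function(x, y, i) electrode(sprintf("e%02d", i), x, y, rad,
                                            kind, s = s),
                xr, yr, seq_along(xr), SIMPLIFY = FALSE)
  electrodeArray(els, layout = list(rule = "grid", nrow = nrow, ncol = ncol,
                                    pitch = pitch, center = center,
                                    angle = angle))
}

#' Generate an electrode array by a placement rule
#'
#' Three placement strategies over an eccentricity range along the
#' horizontal-meridian band of one hemisphere:
#' \describe{
#'   \item{visual_regular}{a uniform lattice in visual degrees, mapped to
#'     cortex (over-represents the periphery on cortex).}
#'   \item{cortical_regular}{a uniform lattice in mm on the cortical sheet
#'     (over-tiles the foveal confluence with overlapping phosphenes).}
#'   \item{optimal}{spacing follows [optimalSpacing()] at each location, so
#'     phosphene center-to-center separation is a constant proportion of
#'     phosphene size; packs electrodes less tightly toward the fovea.}
#' }
#' The lattice pitch is scaled by bisection so the electrode count comes
#' within `tol` of `nTarget`.
#'
#' @param rule placement rule
#' @param nTarget desired electrode count
#' @param eccRange eccentricity range covered along the horizontal meridian
#'   (deg)
#' @param polarRange vertical extent as a fraction of the local eccentricity
#'   (visual rules) — default covers a band `|y| <= 0.4 * ecc`
#' @param map a [RetinoMap-class]
#' @param m,b phosphene-size parameters for the optimal rule
#' @param rad,kind,s electrode properties
#' @param tol acceptable relative deviation of the count from `nTarget`
#' @return an [ElectrodeArray-class]
#' @export
generateArray <- function(rule = c("visual_regular", "cortical_regular",
                                   "optimal"),
                          nTarget = 24, eccRange = c(1, 20),
                          polarRange = 0.4, map = retinoMap(),
                          m = 0.08, b = 0.16, rad = 0.25, kind = "surface",
                          s = 1, tol = 0.15) {
  rule <- match.arg(rule)
  stopifnot(nTarget >= 1, eccRange[1] >= 0, eccRange[2] > eccRange[1])
  build <- function(scale) .buildArrayPositions(rule, scale, eccRange,
                                                polarRange, map, m, b)
  # bisection on the pitch scale so the count lands near nTarget
  lo <- 0.05; hi <- 20
  for (it in 1:60) {
    mid <- sqrt(lo * hi)
    nMid <- nrow(build(mid))
    if (abs(nMid - nTarget) / nTarget <= tol * 0.5) break
    if (nMid > nTarget) lo <- mid else hi <- mid
  }
  pos <- build(mid)
  if (abs(nrow(pos) - nTarget) / nTarget > tol)
    stop(sprintf("infeasible density: rule '%s' gives %d electrodes for target %d",
                 rule, nrow(pos), nTarget))
  els <- lapply(seq_len(nrow(pos)), function(i)
    electrode(sprintf("e%03d", i), pos$x_mm[i], pos$y_mm[i], rad, kind, s = s))
  electrodeArray(els, layout = list(rule = rule, nTarget = nTarget,
                                    eccRange = eccRange, scale = mid,
                                    m = m, b = b))
}

#' @noRd
.buildArrayPositions <- function(rule, scale, eccRange, polarRange, map,
                                 m, b) {
  if (rule == "visual_regular") {
    step <- scale
    ex <- seq(eccRange[1], eccRange[2], by = step)
    pts <- do.call(rbind, lapply(ex, function(x) {
      yy <- seq(-polarRange * x, polarRange * x, by = step)
      if (!length(yy)) yy <- 0
      cbind(x, yy)
    }))
    w <- visualToCortex(complex(real = pts[, 1], imaginary = pts[, 2]), map)
    return(data.frame(x_mm = Re(w), y_mm = Im(w)))
  }
  xCort <- map@k * log(eccRange + map@a)  # cortical x of the ecc range
  if (rule == "cortical_regular") {
    step <- scale
    xs <- seq(xCort[1], xCort[2], by = step)
    pos <- do.call(rbind, lapply(xs, function(x) {
      ecc <- exp(x / map@k) - map@a
      yMax <- abs(map@k * atan2(polarRange * ecc, ecc)) * map@squish
      yy <- seq(-yMax, yMax, by = step)
      if (!length(yy)) yy <- 0
      cbind(x, yy)
    }))
    return(data.frame(x_mm = pos[, 1], y_mm = pos[, 2]))
  }
  # optimal: march along cortical x with local spacing scale*rho(ecc)
  xs <- c(); x <- xCort[1]
  while (x <= xCort[2]) {
    xs <- c(xs, x)
    ecc <- exp(x / map@k) - map@a
    x <- x + scale * optimalSpacing(ecc, m, b, map)
  }
  pos <- do.call(rbind, lapply(xs, function(x) {
    ecc <- exp(x / map@k) - map@a
    step <- scale * optimalSpacing(ecc, m, b, map)
    yMax <- abs(map@k * atan2(polarRange * ecc, ecc)) * map@squish
    yy <- seq(-yMax, yMax, by = step)
    if (!length(yy)) yy <- 0
    cbind(x, yy)
  }))
  data.frame(x_mm = pos[, 1], y_mm = pos[, 2])
}
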
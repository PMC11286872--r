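#' Receptive-field long axis as a function of eccentricity
#'
#' Linear growth of the V1 receptive-field long axis with eccentricity.
#' The default `"keliris"` preset (sigma = 0.16 + 0.08 * ecc, deg) follows
#' single-macaque electrophysiological estimates, the smallest sizes in the
#' literature. The `"meta"` preset is a synthetic stand-in for meta-analytic
#' estimates pooled over older studies, which are larger at every
#' eccentricity (0.5 + 0.1 * ecc); it is illustrative only, not fitted to a
#' specific dataset. The short axis of the receptive field is `sigma/4`.
#'
#' @param ecc eccentricity (deg, >= 0)
#' @param preset "keliris" or "meta"
#' @return long-axis sigma (deg)
#' @examples
#' rfSize(0)   # 0.16 deg at the fovea
#' rfSize(5)   # 0.56 deg
#' @export
rfSize <- function(ecc, preset = c("keliris", "meta")) {
  stopifnot(all(ecc >= 0))
  preset <- match.arg(preset)
  switch(preset,
    keliris = 0.16 + 0.08 * ecc,
    meta = 0.5 + 0.1 * ecc)
}

#' Isotropic radial Gabor filter kernel
#'
#' `F(x, y) = 1/(2*pi*sigmaF^2) * exp(-(x^2+y^2)/(2*sigmaF^2)) *
#' cos(2*pi*r/period)`: a Gaussian envelope times a radial carrier whose
#' spatial period sets the dominant column spacing. The printed form carries
#' a nonzero DC component; with `removeDC = TRUE` (default) the kernel mean
#' is subtracted so the filter is strictly bandpass.
#'
#' @param spacing grid step (mm)
#' @param period carrier spatial period (mm)
#' @param sigmaF envelope standard deviation (mm)
#' @param support half-width of the kernel support in units of sigmaF
#'   (default 6, i.e. a (6+6)*sigmaF wide kernel)
#' @param removeDC subtract the kernel mean
#' @return square odd-sized matrix with attribute `"spacing"`
#' @export
radialGaborKernel <- function(spacing, period = 0.863, sigmaF = 0.5,
                              support = 6, removeDC = TRUE) {
  stopifnot(spacing > 0, period > 0, sigmaF > 0, support >= 3)
  h <- ceiling(support * sigmaF / spacing)
  ax <- seq(-h, h) * spacing
  r <- sqrt(outer(ax^2, ax^2, "+"))
  k <- exp(-r^2 / (2 * sigmaF^2)) / (2 * pi * sigmaF^2) *
    cos(2 * pi * r / period)
  if (removeDC) k <- k - mean(k)
  attr(k, "spacing") <- spacing
  k
}

#' Expected dominant frequency of a map built from noise filtered with a
#' given carrier: peak of |K(k)|^2 (times k^2/2 for x-gradient maps, since
#' differentiation weights the white-noise spectrum by kx^2)
#' @noRd
.spectralPeakFreq <- function(carrierPeriod, sigmaF, spacing,
                              gradientWeight = TRUE, n = 512) {
  k <- radialGaborKernel(spacing, period = carrierPeriod, sigmaF = sigmaF)
  pad <- matrix(0, n, n)
  kr <- nrow(k)
  pad[seq_len(kr), seq_len(kr)] <- k
  P <- Mod(stats::fft(pad))^2
  f <- c(0:(n %/% 2), -((n - 1) %/% 2):-1) / (n * spacing)
  fr <- sqrt(outer(f^2, f^2, "+"))
  if (gradientWeight) P <- P * fr^2
  df <- 1 / (n * spacing)
  bins <- round(fr / df)
  prof <- tapply(as.vector(P), as.vector(bins), mean)
  fbin <- as.numeric(names(prof)) * df
  keep <- fbin > 2 * df & fbin <= 1 / (2 * spacing)
  prof <- prof[keep]; fbin <- fbin[keep]
  i <- which.max(prof)
  if (i > 1 && i < length(prof)) {
    y <- log(prof[(i - 1):(i + 1)])
    denom <- y[1] - 2 * y[2] + y[3]
    if (abs(denom) > 0)
      return(fbin[i] + 0.5 * (y[1] - y[3]) / denom * (fbin[i + 1] - fbin[i]))
  }
  fbin[i]
}

#' Carrier period such that maps built from x-gradients of the filtered
#' noise have their dominant spatial period at `targetPeriod`. The gradient
#' weights the spectrum by k^2 and shifts the radial power peak upward, so
#' the carrier must sit at a slightly lower frequency than the target; this
#' solves for it from the kernel spectrum alone (no noise involved).
#' @noRd
.carrierCache <- new.env(parent = emptyenv())

.calibrateCarrier <- function(targetPeriod, sigmaF, spacing) {
  key <- paste(targetPeriod, sigmaF, spacing, sep = "|")
  hit <- .carrierCache[[key]]
  if (!is.null(hit)) return(hit)
  fTarget <- 1 / targetPeriod
  g <- function(p) .spectralPeakFreq(p, sigmaF, spacing) - fTarget
  root <- stats::uniroot(g, interval = c(targetPeriod * 0.8, targetPeriod * 3),
                         tol = 1e-4)$root
  .carrierCache[[key]] <- root
  root
}

#' Seeded evaluation with RNG state restored afterwards
#' @noRd
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Circular FFT filtering of a complex field with a centered kernel
#' @noRd
.fftFilter <- function(field, kernel) {
  nr <- nrow(field); nc <- ncol(field)
  kr <- nrow(kernel); kc <- ncol(kernel)
  if (kr > nr || kc > nc)
    stop("sheet extent too small for the filter support")
  pad <- matrix(0, nr, nc)
  pad[seq_len(kr), seq_len(kc)] <- kernel
  # center the kernel at (1, 1) with wraparound
  pad <- pad[((seq_len(nr) - 1 + (kr - 1) / 2) %% nr) + 1,
             ((seq_len(nc) - 1 + (kc - 1) / 2) %% nc) + 1]
  stats::fft(stats::fft(field) * stats::fft(pad), inverse = TRUE) / (nr * nc)
}

#' Central-difference gradient along rows (cortical x), periodic ends
#' @noRd
.gradX <- function(m, spacing) {
  n <- nrow(m)
  (m[c(2:n, 1), , drop = FALSE] - m[c(n, 1:(n - 1)), , drop = FALSE]) /
    (2 * spacing)
}

#' Generate a cortical sheet with orientation, ocular-dominance and
#' on/off-subunit maps
#'
#' One complex white-noise field (independent standard complex Gaussian per
#' lattice cell, seeded) is bandpass filtered with the radial Gabor at the
#' dominance-column period to yield the orientation map (half the angle of
#' the filtered field, so orientations span (-pi/2, pi/2]) and the ocular
#' dominance map (the x-gradient of the real part, z-scored and passed
#' through the normal CDF). The same noise filtered at half the period
#' yields the on/off-subunit separation (from the angle, giving
#' exponentially distributed magnitudes scaled by receptive-field area) and
#' the on/off balance map (x-gradient through the normal CDF).
#'
#' `odPeriod` is the dominant spatial period of the resulting ocular
#' dominance maps. Because the x-gradient weights the noise spectrum by
#' kx^2 (shifting the radial power peak above the filter carrier), the
#' carrier period is calibrated analytically from the kernel spectrum so
#' the maps' dominant period lands at `odPeriod`; the calibrated carrier is
#' recorded in `params$carrier`.
#'
#' The noise lives on a fixed internal lattice (`noiseSpacing`), and the
#' filtered field is bilinearly interpolated to the requested grid, so
#' refining `spacing` resamples the same structure instead of drawing new
#' noise.
#'
#' @param xRange,yRange cortical extent (mm), e.g. `c(10, 30)`
#' @param spacing grid step (mm)
#' @param map a [RetinoMap-class] giving each location its visual-field
#'   position
#' @param odPeriod mean ocular-dominance column period (mm)
#' @param sigmaF bandpass envelope width (mm)
#' @param seed RNG seed (maps are deterministic given the seed)
#' @param rfPreset receptive-field size preset, see [rfSize()]
#' @param noiseSpacing internal noise-lattice step (mm)
#' @return a [CorticalSheet-class]
#' @examples
#' sh <- makeCorticalSheet(c(20, 26), c(-3, 3), spacing = 0.25, seed = 1)
#' range(sh@wOd)
#' @export
makeCorticalSheet <- function(xRange, yRange, spacing = 0.1,
                              map = retinoMap(), odPeriod = 0.863,
                              sigmaF = 0.5, seed = 1,
                              rfPreset = "keliris", noiseSpacing = 0.1) {
  stopifnot(spacing > 0, length(xRange) == 2, length(yRange) == 2)
  if (diff(xRange) < 6 * sigmaF || diff(yRange) < 6 * sigmaF)
    stop("sheet extent must cover at least the filter support (6*sigmaF)")
  # canonical noise lattice, padded a little beyond the sheet
  padMm <- 3 * sigmaF
  nx0 <- seq(xRange[1] - padMm, xRange[2] + padMm, by = noiseSpacing)
  ny0 <- seq(yRange[1] - padMm, yRange[2] + padMm, by = noiseSpacing)
  n0 <- length(nx0) * length(ny0)
  noise <- .withSeed(seed, matrix(
    complex(real = stats::rnorm(n0), imaginary = stats::rnorm(n0)),
    nrow = length(nx0)))
  carrier <- .calibrateCarrier(odPeriod, sigmaF, noiseSpacing)
  k1 <- radialGaborKernel(noiseSpacing, period = carrier, sigmaF = sigmaF)
  k2 <- radialGaborKernel(noiseSpacing, period = carrier / 2, sigmaF = sigmaF)
  f1 <- .fftFilter(noise, k1)
  f2 <- .fftFilter(noise, k2)

  xmm <- seq(xRange[1], xRange[2], by = spacing)
  ymm <- seq(yRange[1], yRange[2], by = spacing)

  ip <- function(m) .bilinear(nx0, ny0, m, xmm, ymm)
  f1r <- ip(Re(f1)); f1i <- ip(Im(f1))
  f2r <- ip(Re(f2)); f2i <- ip(Im(f2))

  theta <- atan2(f1i, f1r) / 2            # (-pi/2, pi/2]
  zsc <- function(m) (m - mean(m)) / stats::sd(m)
  wOd <- stats::pnorm(zsc(.gradX(f1r, spacing)))
  wOnOff <- stats::pnorm(zsc(.gradX(f2r, spacing)))

  w <- outer(xmm, ymm, function(x, y) complex(real = x, imaginary = y))
  z <- cortexToVisual(w, map)
  zRe <- matrix(Re(z), length(xmm)); zIm <- matrix(Im(z), length(xmm))
  ecc <- sqrt(zRe^2 + zIm^2)
  sigmaRf <- matrix(rfSize(ecc, rfPreset), length(xmm))

  u <- atan2(f2i, f2r)
  aRf <- pi * sigmaRf * (sigmaRf / 4)     # RF ellipse area (deg^2)
  absU <- pmax(abs(u) / pi, 1e-12)
  deltaOnOff <- aRf * sign(u + (u == 0)) * (-log(absU)) / 2

  new("CorticalSheet", xmm = xmm, ymm = ymm, theta = theta, wOd = wOd,
      wOnOff = wOnOff, deltaOnOff = deltaOnOff, sigmaRf = sigmaRf,
      zRe = zRe, zIm = zIm, map = map, spacing = spacing, seed = seed,
      params = list(odPeriod = odPeriod, sigmaF = sigmaF, carrier = carrier,
                    rfPreset = rfPreset, noiseSpacing = noiseSpacing))
}

#' Bilinear interpolation of a matrix from axes (x0, y0) to (x1, y1)
#' @noRd
.bilinear <- function(x0, y0, m, x1, y1) {
  ix <- findInterval(x1, x0, all.inside = TRUE)
  iy <- findInterval(y1, y0, all.inside = TRUE)
  tx <- (x1 - x0[ix]) / (x0[ix + 1] - x0[ix])
  ty <- (y1 - y0[iy]) / (y0[iy + 1] - y0[iy])
  tx <- pmin(pmax(tx, 0), 1); ty <- pmin(pmax(ty, 0), 1)
  m00 <- m[ix, iy, drop = FALSE]; m10 <- m[ix + 1, iy, drop = FALSE]
  m01 <- m[ix, iy + 1, drop = FALSE]; m11 <- m[ix + 1, iy + 1, drop = FALSE]
  TX <- matrix(tx, length(x1), length(y1))
  TY <- matrix(ty, length(x1), length(y1), byrow = TRUE)
  (1 - TX) * (1 - TY) * m00 + TX * (1 - TY) * m10 +
    (1 - TX) * TY * m01 + TX * TY * m11
}

setMethod("show", "CorticalSheet", function(object) {
  cat(sprintf(
    paste0("CorticalSheet: %d x %d grid, x [%g, %g] mm, y [%g, %g] mm, ",
           "spacing %g mm\n  eccentricity %.2f-%.2f deg | OD period %g mm | ",
           "seed %d | rf preset '%s'\n"),
    length(object@xmm), length(object@ymm),
    min(object@xmm), max(object@xmm), min(object@ymm), max(object@ymm),
    object@spacing, min(sqrt(object@zRe^2 + object@zIm^2)),
    max(sqrt(object@zRe^2 + object@zIm^2)),
    object@params$odPeriod, as.integer(object@seed), object@params$rfPreset))
})

#' Estimate the dominant column period of a map
#'
#' Peak of the radially averaged power spectrum of the (mean-removed) map,
#' refined by parabolic interpolation over the peak's neighbours, converted
#' to a spatial period.
#'
#' @param map a numeric matrix (e.g. the `wOd` slot of a sheet)
#' @param spacing grid step (mm)
#' @param fMin lowest radial frequency considered (cycles/mm); defaults to
#'   twice the frequency resolution, excluding the DC region
#' @return estimated period (mm)
#' @export
estimateColumnPeriod <- function(map, spacing, fMin = NULL) {
  stopifnot(is.matrix(map), spacing > 0)
  if (stats::var(as.vector(map)) < 1e-14)
    stop("flat map: no spectral peak")
  m <- map - mean(map)
  nr <- nrow(m); nc <- ncol(m)
  P <- Mod(stats::fft(m))^2
  fx <- c(0:(nr %/% 2), -((nr - 1) %/% 2):-1) / (nr * spacing)
  fy <- c(0:(nc %/% 2), -((nc - 1) %/% 2):-1) / (nc * spacing)
  fr <- sqrt(outer(fx^2, fy^2, "+"))
  df <- 1 / (max(nr, nc) * spacing)
  if (is.null(fMin)) fMin <- 2 * df
  bins <- round(fr / df)
  prof <- tapply(as.vector(P), as.vector(bins), mean)
  fbin <- as.numeric(names(prof)) * df
  keep <- fbin >= fMin & fbin <= 1 / (2 * spacing)
  prof <- prof[keep]; fbin <- fbin[keep]
  if (!length(prof)) stop("no usable frequency bins")
  i <- which.max(prof)
  fPeak <- fbin[i]
  if (i > 1 && i < length(prof)) {
    # parabolic refinement on log power
    y <- log(prof[(i - 1):(i + 1)] + .Machine$double.xmin)
    denom <- y[1] - 2 * y[2] + y[3]
    if (abs(denom) > 0) {
      shift <- 0.5 * (y[1] - y[3]) / denom
      fPeak <- fbin[i] + shift * (fbin[i + 1] - fbin[i])
    }
  }
  unname(1 / fPeak)
}
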
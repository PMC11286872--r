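---
title: "A virtual-patient model of V1 electrical stimulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A virtual-patient model of V1 electrical stimulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cortivis)
```

`cortivis` simulates what a person perceives when primary visual cortex (V1)
is stimulated electrically through an implanted electrode: the location,
size, shape and brightness of the resulting phosphene, and how these depend
on the pulse train, the electrode geometry, and where on the cortex the
electrode sits. It is a "virtual patient": a forward model assembled from
the neurophysiological architecture of V1 rather than fit to any one
stimulation dataset, intended for exploring prospective prosthesis designs.

## The temporal cascade

A biphasic pulse train `p(t)` (amplitude in uA, phase width in ms, rate in
Hz, duration in s; cathodic-first by convention) is converted to perceived
brightness over time in four stages.

**1. Fast current integration.** Membrane depolarization is modeled as a
one-stage leaky integrator,
$$\frac{dR_1}{dt} = p(t) - \frac{R_1}{\tau_1}, \qquad \tau_1 = 0.3\ \mathrm{ms},$$
solved with an exponential integrator that is exact for piecewise-constant
input (the sampled waveform), so the numerical trace matches the per-phase
closed form to machine precision at the sampling resolution
(`dt = 0.01` ms by default, which also resolves the 0.25-ms phases used in
threshold work).

**2. Spiking strength and refractoriness.** Population spiking is read out
at the offset of the positive phase of each pulse — placed analytically
from the train geometry rather than by peak-picking, so event timing does
not depend on `dt`. The strength is the (rectified) value of `R1` there.
Successive events are attenuated by the refractory factor
$$1 - e^{-\tau_r (\Delta + \delta)},$$
with the interval `Delta` in seconds. Printed parameter tables in this
model family are inconsistent about the refractory constants (a rate of
100, "50 ms"); only a *rate* of `tau_r = 50` s^-1 with `delta = 0.001` s
reproduces the worked value `1 - exp(-50*(1/50 + 0.001)) = 0.6501` for
50 Hz stimulation, so those are the defaults and both are configurable.
The first event of a train has no predecessor and is left unattenuated.

**3. Slow integration.** The event train is convolved with the impulse
response of an `n`-stage leaky integrator — a gamma density with shape
`n = 3` and scale `tau2 = 150` ms, evaluated exactly at each output sample
rather than binned. `tau2 = 150` ms is the value stated jointly with the
kernel definition; a parameter table in the same family lists 25 ms, which
is exposed as an option (`temporalParams(tau2 = 25)`). The slow stage is the
model's "memory": percepts outlast 50-ms bursts by hundreds of ms, which is
also why sequentially traced letter shapes remain visible as a whole.

**4. Compression.** Brightness is a scaled hyperbolic tangent,
$$\mathrm{brightness}(t) = s_{out} \tanh\!\left(\frac{s\,R_2(t)}{p}\right),$$
with `sOut = 10` matching 1-10 clinical rating scales, `pDiv = 15.6`, and
sensitivity `sIn = 0.57` by default. Everything before this stage is linear
in amplitude, which the implementation exploits in two places: percept
movies factor exactly into one spatial field times one temporal drive
(an exact restructuring, not an approximation), and detection thresholds
can be bracketed quickly because the pre-compression response scales
linearly with amplitude.

**Detection and drawing.** A stimulus is detectable when the maximum
sensitivity-scaled pre-compression response crosses `thetaThresh`;
`calibrateThetaThresh()` fixes that constant as the response of a
"standard" electrode — 3 uA threshold for a 50 Hz, 0.25 ms, 0.5 s
cathodic-first train at `s = 0.43` — so a threshold search on the standard
electrode returns 3 uA by construction. Detection is evaluated
pre-compression; near threshold the nonlinearity is in its linear range, so
the choice is immaterial there. Drawing (shape report) instead thresholds
the compressed image at `thetaDraw = 1`, the dimmest reportable rating.
These two anchors are numerically far apart: with these constants a percept
only becomes drawable orders of magnitude above its detection current,
consistent with drawn phosphenes in the literature being collected at
mA-level currents while microelectrode detection thresholds sit at a few
uA. Size experiments therefore reference their amplitudes to each
configuration's *drawing-threshold* current (`ampFactors`), or to a fixed
absolute current (`amps`) when comparing electrode radii.

Two empirical regularities follow from the constants rather than being
imposed: the charge per phase needed to detect a train,
$Q \propto pw / (1 - e^{-pw/\tau_1})^2$, is minimized near
$pw^* = 1.256\,\tau_1 \approx 0.38$ ms (charge efficiency peaks near
0.4 ms), and amplitude savings per frequency doubling shrink markedly
beyond ~64 Hz as the refractory factor eats into the extra pulses.

## Retinotopy

Visual space (complex `z`, degrees) maps to the flattened cortical sheet
(complex `w`, mm) through `w = k log(z + a)` with `k = 15` mm,
`a = 0.5` deg, and an optional compression of the cortical y axis
(`squish`). The map and its inverse are exact inverses; cortical
magnification on the horizontal meridian is `k/(ecc + a)`. One sheet
represents one hemisphere (right hemifield on the left sheet); the
published parameter set that best localized a 24-electrode surface grid
(`a = 0.15, k = 16.6, squish = 0.63`) ships as the `"beauchamp2020"`
preset and is not re-fit. Stored cortical coordinates are the raw map
output (fovea at `k log(a)`, negative x); display code may translate them.

## Synthesizing the cortical sheet

All per-location neuronal properties derive from a single complex
white-noise field, filtered with an isotropic radial Gabor
(envelope SD `sigmaF`, carrier period tied to `odPeriod`):

* **orientation** — half the angle of the filtered field, mapped into
  `(-pi/2, pi/2]` (the angle of a complex number spans 2*pi but orientation
  is pi-periodic; halving gives the usual pinwheel topology);
* **ocular dominance** — the x-derivative of the real part, z-scored and
  passed through the normal CDF, giving a balanced map in [0, 1];
* **on/off subunit separation and balance** — the same noise filtered at
  half the period; the angle `u` of that field is uniform, so
  `-log(|u|/pi)` is Exp(1) and the signed separation
  `A_rf * sign(u) * (-log(|u|/pi)) / 2` has exponentially distributed
  magnitude (rate 2, in units of the receptive-field ellipse area
  `A_rf = pi * sigma_rf * sigma_rf/4`): small separations (complex-like
  cells) are common, large ones (simple-like) rare. The printed form of
  this formula divides by its own left-hand symbol; the rate constant 2
  from the parameter table is used instead. The balance map comes from the
  x-gradient of the same second field through the normal CDF.

Two numerical choices matter here. First, the stated `odPeriod = 0.863` mm
is defined as "mm per mean dominance column period" — a property of the
*maps*. Because the x-derivative weights the noise spectrum by `kx^2`, the
radial power peak of the gradient field sits above the filter carrier; the
carrier period is therefore calibrated analytically from the kernel
spectrum (no noise involved) so that the maps' dominant period lands at
`odPeriod`. Without this correction the maps come out near 0.75 mm.
Second, the envelope width is taken from the parameter table's bandpass
scale (`sigmaF = 0.5` mm); the running text calls it "3 cycles/mm", which
is dimensionally a bandwidth, not an envelope SD — the 0.5-mm scale gives
columnar (neither sinusoidal nor structureless) maps and is the documented
default. The filter kernel's mean is subtracted so it is strictly bandpass
(the printed Gabor has nonzero DC).

The noise lives on a fixed internal lattice (0.1 mm), and the filtered
field is interpolated to the requested grid: refining the grid resamples
the same structure rather than drawing new noise, so maps are consistent
across resolutions (correlation > 0.9 on shared points). Maps are
deterministic given the seed, which is recorded in the sheet.

One property often attributed to such maps did not survive testing: the
pointwise angle between the ocular-dominance gradient and the orientation
gradient is at chance (~45 deg), not concentrated near 90 deg — for a
locally plane-wave bandpass field both gradients align with the local wave
vector, so the construction cannot produce pointwise orthogonality. The
test suite asserts the properties the construction does guarantee.

Receptive-field size grows linearly with eccentricity,
`sigma_rf = 0.16 + 0.08 * ecc` deg (single-macaque electrophysiology, the
smallest published values), with short axis `sigma_rf/4`. The `"meta"`
preset is a synthetic stand-in for the larger meta-analytic estimates
(0.5 + 0.1 * ecc); it is illustrative, not fit to a specific dataset.

## Receptive fields and percept rendering

Each location contributes a two-subunit receptive field: ON and OFF
anisotropic Gaussians (long axis `sigma_rf`, short axis `sigma_rf/4`,
oriented at the local preferred orientation) displaced by
`±delta_onoff/2` along the short axis. Each subunit is normalized to unit
mass individually (the "normalized by area" wording admits per-subunit or
per-cell normalization; per-subunit is used, so the ON:OFF weighting below
is exact). Only excitatory components are modeled. The percept's spatial
field is
$$R_{sp}(x,y) = \sum_{\mathrm{locations}} I \cdot \mathrm{cellArea} \cdot
\left[w_{on/off}\,\mathrm{ON} - \omega\,(1 - w_{on/off})\,\mathrm{OFF}\right]
\cdot \mathrm{eyeWeight},$$
with `omega = 0.8`: OFF subunits contribute *negative* (darker than
background) intensity, which is what produces the irregular percepts with
dark regions reported for very small electrodes, while the 0.8 weighting
keeps suprathreshold percepts net-bright. The grid-cell area factor makes
the sum a discrete surface integral, so refining the cortical grid does not
change percept intensity. The default binocular output blends the eyes
(`wOd * LE + (1 - wOd) * RE`, summing to 1); per-eye frames are available.

Frames are `compress(R_sp * drive(t))`, where `drive(t)` is the slow
response of the train per unit amplitude — the exact separable form.
Multi-electrode schedules superpose the per-electrode spatiotemporal drives
*before* compression. The rendering grid scales with the local receptive
field (pixel spacing = smallest short axis / 5, clamped to
[0.004, 0.15] deg): a fixed 0.02-deg grid would be needlessly fine at 30
deg eccentricity (million-pixel frames) and too coarse at the fovea; a
resolution guard rejects grids coarser than a quarter short axis.

Percepts are quantified two ways, as in the source literature: image
moments of the drawing-thresholded binary image (`|I| >= thetaDraw`, so
dark lobes count toward the drawn shape; ellipse axes use the solid-ellipse
convention, size = mean of major and minor diameters), and a threshold-free
least-squares isotropic Gaussian fit. The Gaussian is fit to the *absolute*
intensity: for strongly fragmented ON/OFF percepts the positive part alone
is so patchy that the best-fitting Gaussian degenerates toward zero
amplitude, while the absolute intensity describes the affected region
robustly. Empty (all-subthreshold) frames yield a sentinel row, not an
error.

## Electrodes, current spread and array design

Current falls off with distance `d` from the nearest point of the circular
electrode footprint as `I = I_input / (1 + K d^2)`, with a plateau over the
footprint; `K = 675` for surface electrodes and `1e5` (extremely narrow
spread) for depth electrodes, which are otherwise modeled as surface
points. `K` is stored as a bare number acting as mm^-2 with distances in
mm, matching how the constant is printed (uA/mm^2) but used.

Optimal cortical sampling spaces electrodes so that phosphene
center-to-center separation is a constant proportion of phosphene size:
$$\rho(x) = (m x + b)\,\frac{k}{x + a},$$
with `m = 0.08`, `b = 0.16`. This gives 4.8 mm at the fovea, 1.3 mm at 20
deg, and a 1.2 mm asymptote — optimal arrays pack electrodes *less*
densely toward the foveal representation. The first-order rule stays
within 10% of the exact map-based spacing for eccentricities >= 1 deg. (At
1 deg the closed form evaluates to ~3.2 mm with these constants, not the
2.2 mm sometimes quoted; the 20-deg value is consistent, and only it is
used as an anchor.) `generateArray()` implements uniform-in-visual-field,
uniform-on-cortex and optimal layouts, scaling the pitch so electrode
counts match a target within 15%.

## What the experiments show — and their problem sizes

The drivers reproduce the structure of the source experiments at sizes
chosen to run comfortably on one CPU:

* strength-duration and threshold-frequency curves (temporal-only; the
  spatial factor is a constant that cancels for single electrodes, so
  these use the temporal response directly);
* threshold separability: threshold matrices over pulse width x frequency
  for electrodes differing only in sensitivity are rank-1 (bisection run
  to 1e-9 relative tolerance for that check; the default search tolerance
  is 1%);
* sensitivity recovery: noiseless thresholds recover a known `s` to <1%,
  and the median over 20 replicates under 10% lognormal noise stays within
  5%;
* phosphene size versus amplitude (monotone), eccentricity (linear,
  R^2 > 0.9 for 0.25-mm electrodes over 1-30 deg), and electrode radius
  (insensitive below 0.25 mm, growing above 1 mm; run with depth-style
  narrow spread and drive-matched amplitudes so the stimulated-cortex
  radius tracks the electrode radius, and measured with the Gaussian fit,
  as in the source's radius analysis);
* ocular-dominance periodicity: dominant spatial period ~0.863 mm averaged
  over five 20 x 20 mm sheets at 0.1 mm spacing.

Sheets for size experiments are (2 x (max radius + 1.6 mm))-wide patches at
0.1 mm spacing sharing one noise draw per eccentricity, so radius
comparisons see the same neurons.

## What the synthetic maps do and do not capture

The generator reproduces the *statistics* the model needs — column
periodicity, balanced eye dominance, exponentially distributed subunit
separations, linear receptive-field growth — from seeded noise. It does not
reproduce any individual's map layout, layer-specific physiology,
electric-field interactions between electrodes, anodic/cathodic threshold
asymmetries, or desensitization over seconds-to-minutes of repeated
stimulation (explicitly out of scope for this model family). Passing tests
therefore validate the model's internal structure and its printed anchor
values, not patient-level prediction: the published patient correlations
require the original studies' summary data files, which are not bundled.

## Degenerate inputs and tie-breaks

Zero-amplitude trains produce zero events, zero response and the empty
percept; `u = 0` in the separation formula gets sign +1; interpolation at
event times clamps to the trace end; threshold search returns a not-found
sentinel above a 10-mA ceiling (configurable); all-subthreshold frames
return the empty-ellipse sentinel; a flat map raises a no-peak error in
period estimation. Interphase gaps default to 0 (none is stated for this
model family).
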
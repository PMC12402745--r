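---
title: "Sensitivity-compensated quantitative iRAI: models, assumptions, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sensitivity-compensated quantitative iRAI: models, assumptions, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Ionizing radiation acoustic imaging (iRAI) maps the dose deposited by pulsed
x-ray beams by listening to the pressure transients that the microsecond
energy deposition induces in tissue. A 2D matrix array transducer (MAT)
receives these transients and a delay-and-sum (DAS) beamformer turns them
into a volumetric image. The catch for *quantitative* dose mapping is that
the array's detection sensitivity is strongly position dependent: the same
dose produces a bright image near the array's focal zone and a dim one at
the periphery. This package implements the full correction pipeline:

1. characterize the volumetric detection sensitivity of the array, both by a
   dynamic-focusing sweep simulation and by a virtual reproduction of the
   point-source measurement protocol;
2. invert the normalized sensitivity map into a voxel-wise correction-factor
   volume;
3. forward-model radiation-induced channel data from synthetic dose volumes,
   reconstruct by DAS with envelope detection, and multiply by the
   correction factors;
4. quantify agreement with the planned dose (DVH, DVH-RMSE, 3D global gamma,
   SSIM, isodose contours, region-mean amplitudes, midline profiles).

Everything is synthetic: the package ships no data and generates all study
inputs in code.

## The instrument model

The array is a 32 x 32 grid of 3.45 mm square elements with 0.2 mm kerf
(3.65 mm pitch, 11.66 cm aperture), centred at the origin in the plane
z = 0, receiving at a 0.35 MHz center frequency with 50% fractional
bandwidth (-6 dB). The receive impulse response is a Gaussian-enveloped
cosine whose -6 dB amplitude-spectrum width equals the fractional bandwidth;
with bandwidth b and center frequency f0 the envelope standard deviation is
`sqrt(2 log 2) / (pi * b * f0)` (about 2.14 us here).

**Element angular response.** Each element is modelled as a separable
far-field aperture: the amplitude factor toward a direction with direction
cosines (ux, uy) is `sinc(pi a/lambda ux) * sinc(pi a/lambda uy)`, evaluated
at the center frequency, with an optional soft-baffle `cos(theta)` factor.
The width `a` of this response is the one genuinely open parameter of the
instrument model. The far-field sinc of the *bare* 3.45 mm element
(`element_directivity(spec, theta, size = spec$element_size)`) is much
wider-angled than assembled matrix arrays exhibit in practice — matching
stacks and inter-element coupling narrow the acceptance — and, taken at
face value, it places the simulated on-axis sensitivity maximum at about
4 cm and makes sensitivity *fall* monotonically with depth. That contradicts
the instrument's measured behaviour: its sensitivity peaks around 15 cm
depth, and beam amplitudes *rise* with depth before compensation. We
therefore treat the effective width as a calibration constant,
`transducer_spec()$directivity_size`, and set its default (8 mm) so that the
simulated on-axis sensitivity peaks at 15 cm. This is the only calibrated
parameter in the package; every downstream behaviour (rising pre-compensation
depth trend, compensation flattening it) emerges from it rather than being
fitted. Users who want the idealized bare-element model can set
`directivity_size = element_size`.

## Detection sensitivity

**Dynamic-focusing sweep** (`simulate_sensitivity_map()`): steering angles
in azimuth and elevation run over the half-open grid [0°, 180°) (so a 0.5°
step gives 360 angles per axis and 129600 events). For each event the array
is focused dynamically — the focal point tracks range along the steered
direction, the receive-beamforming analogue of depth-tracking focal delays —
and the field value at a voxel is the envelope peak of the coherent element
sum, each element weighted by 1/r and its angular response. On the steered
ray the delays align exactly and the value reduces to `sum_i D_i(x)/r_i(x)`.
The map is the voxel-wise maximum over all events, normalized to 1.

The compiled kernel evaluates, per voxel, only events whose steering angles
lie within `window_deg` (default: 1.5°, or one step for coarse plans) of the
voxel's own direction angles: a focused beam steered several beamwidths away
(the array's beamwidth is about 2° FWHM at 0.35 MHz) cannot beat the aligned
events, and the tests verify pruned and exhaustive sweeps agree. The
narrowband evaluation at focal-zone passage time is validated against a
brute-force delayed-pulse superposition oracle.

**Virtual point-source protocol** (`virtual_point_source_map()`): a point
source is placed at each lattice position (the physical protocol used a
2.5 cm lattice over 15 x 15 x 25 cm, i.e. 7 x 7 x 11 positions), its channel
data are simulated, optionally corrupted with white noise and averaged (1000
pulses through the 4:1 multiplexer are equivalent to 250 full acquisitions),
the volume is reconstructed, and the image maximum represents the
sensitivity at that position. Acoustic reciprocity is assumed throughout:
the transmit-focused field stands in for receive sensitivity, which is why
the sweep map and the point-source map agree (a test checks this on a coarse
configuration). The sparse lattice is densified by trilinear interpolation
with edge clamping — the physical protocol does not state this step, so it
is our choice.

**Correction factors** (`correction_factors()`): the voxel-wise reciprocal
of the normalized map, floored at `floor_epsilon` (default 0.05, so factors
lie in [1, 20]). Unbounded reciprocals would amplify whatever lives in
near-zero-sensitivity voxels — noise in a measurement, reconstruction
artifacts in a simulation; floored voxels are counted and reported. The
simulated and virtual maps are each normalized to their own maximum before
inversion.

## Forward model

The phantom is homogeneous solidified vegetable oil (c = 1445 m/s,
rho = 920 kg/m^3) in a 17 x 17 x 20 cm box; the C-shape study uses a
15 x 15 x 15 cm volume starting 2.5 cm in front of the array. Initial
pressure is `p0 = Gamma * rho * D` (Gy = J/kg); the Grueneisen parameter
defaults to 0.9, a representative value for lipid-like media (the medium's
Grueneisen is not stated anywhere authoritative, so it only scales
amplitudes, which are relative throughout).

Wave propagation is exact retarded-potential superposition in a homogeneous
lossless medium: each source voxel contributes `p0 V/(4 pi r)` delayed by
`r/c` and weighted by the element's angular response. This replaces a
pseudospectral full-wave solver; for a homogeneous medium superposition is
exact up to discretization, and the tests exploit that (two-voxel traces are
the sum of one-voxel traces to machine precision). The 4 us x-ray pulse
violates stress confinement, so the impulse response is convolved with the
time derivative of the pulse envelope (default: Hann of 4 us at 330 Hz
repetition; one period is simulated). The combined kernel is applied
zero-phase, so a point source at range r peaks at exactly t = r/c.

Two discretization rules matter:

* **Source sampling.** Treating voxels as point sources requires spacing at
  or below lambda/4 (about 1 mm at 0.35 MHz in oil); `propagate()` warns
  otherwise. The study driver therefore discretizes dose at 1 mm for the
  forward model while imaging on the 5 mm working grid. At 5 mm the
  "extended beam" degenerates into a sparse set of interfering point
  scatterers and extended-source amplitudes become unreliable.
* **Receive bandwidth.** `propagate()` by default also convolves with the
  element receive impulse response — the physical receive chain. The study
  driver (`run_experiment()`) disables it: with the 0.35 MHz/50% band-pass
  applied, uniform dose regions wider than the pulse footprint (beams of
  2 cm and above, the C-shape arms) reconstruct as hollow shells, because
  the band-pass removes the low spatial frequencies that encode their
  interiors, and region means, profiles and plan comparisons lose their
  meaning. The wideband setting corresponds to recording the pressure field
  itself, the convention of full-wave simulation studies; the flag
  `forward$apply_receive_ir` exposes both.

`acquire()` adds white noise per acquisition and averages; the averaged
noise is drawn in one step with sd `noise_std/sqrt(n)`, which is exactly the
distribution of the mean of n draws.

## Reconstruction and compensation

`das_reconstruct()` computes, per voxel, the magnitude of the sum over
elements of the analytic (complex) trace sampled at t = r/c with linear
inter-sample interpolation — complex/analytic DAS, i.e. envelope detection
on the beamformed signal. The physical protocol's wording leaves the order
of envelope detection and summation open; complex DAS is chosen for phase
robustness, and an RF-summation mode is available for comparison. No receive
apodization is applied. Delays beyond the trace support zero the voxel and
are counted. `compensate()` multiplies voxel-wise by the correction factors,
refuses double application, and records the flag in the output (and in the
NIfTI sidecar on disk).

For a point target the DAS peak equals the sweep map's value at that
position up to a constant, so compensation is exactly self-consistent for
point-like features. For extended dose regions it is not: the image
brightness also carries the position-dependent width of the point-spread
function and the beam's own edge structure, which a voxel-wise reciprocal
cannot remove. This is visible in the results (below) and is, we believe, a
genuine property of the method rather than an artifact of this
implementation.

## Phantoms

`square_beam_dose()` builds vertically-directed uniform beam columns
(entering along +y, crossing the imaging axis); `beam_study_layouts()`
enumerates the three families: seven depths (5-17 cm, 2 cm steps) on the
axis, seven lateral offsets (±6 cm, 2 cm steps) at 11 cm depth, and five
field sizes (1-5 cm) at 11 cm depth. The depth-dose model defaults to
uniform — the beam column itself is the imaging target, and a uniform column
cleanly separates sensitivity effects from beam physics; an exponential
model with a configurable effective attenuation is available. Beams deliver
2.26 Gy per measurement.

`c_shape_dose()` builds the C-shaped plan: an annular-sector prism (target
wrapping around a spared central structure), 21.6 Gy maximum. The reference
plan gives only the topology and maximum dose, so the geometry — outer
radius 5 cm, inner 2.5 cm, 90° gap opening toward +y, 5 cm height, 3 mm
Gaussian edge — is this package's synthetic stand-in, and is documented as
such.

## Quantification

* `dvh()`: complementary cumulative histogram, 101 equally spaced levels
  from 0 to the maximum; `dvh_rmse()` is the RMS difference of volume
  fractions, in percentage points (the reference values 6.92/4.85 are
  printed unitless; this is our reading).
* `gamma_index()`: global 3D gamma with 5%/5 mm criteria by default, dose
  difference normalized to the reference maximum, candidate displacements on
  a 1/3-voxel lattice within 3 x DTA, trilinear interpolation of the
  evaluated volume, early exit on the sorted distance term. A low-dose
  threshold (default 10% of the reference maximum) selects the voxels
  entering the headline pass rate; the all-voxel rate is also reported. An
  exhaustive brute-force search is kept as a test oracle and matches the
  kernel to 1e-10 on small grids.
* `ssim_index()`: Gaussian-windowed (sigma 1.5, 11 x 11) SSIM with the
  standard stabilization constants, slice-wise on 3D inputs.
* `isodose_contour()`: marching-squares contours at a fraction of the image
  maximum (0.8 is the clinical benchmark level).
* `region_mean_amplitude()` with `beam_region_mask()`: the per-position
  summary averages the image over the beam's central cross-section (dose at
  or above half-maximum, |y| ≤ field_size/2), mirroring quantification on
  cross-sectional beam images; full-column masks are dominated by the
  column's ends outside the elements' acceptance cone.
* `line_profile()`: midline profiles along the depth axis; plateau slopes
  are fitted inside the nominal beam edges with one voxel of margin and
  normalized by the plateau mean.

## Study conditions and what the tests show

The default configuration (`default_run_config()`) runs all volumes at 5 mm
voxels, the sweep at 0.5° with a 1.5° pruning window, the forward model at
1 mm sources, noiseless. At these sizes the full test suite (including the
end-to-end studies) runs in minutes on one CPU. On the synthetic twin:

* Pre-compensation depth means rise steeply (about 0.20 to 1 over 5-17 cm)
  and lateral means fall toward the edges — the sensitivity signature the
  correction targets. Compensation cuts the coefficient of variation about
  three-fold in both families (depth 0.43 to 0.14, lateral 0.36 to 0.10).
* Post-compensation means do **not** all land within ±10% of a common
  constant (depth spans 0.67-1, lateral 0.80-1), and size-family plateau
  slopes flatten by about 1.5x rather than the five-fold the measured data
  show: the residuals are the extended-source effects described above, which
  point-sensitivity compensation cannot address. We report this as a limit
  of the method under idealized matched physics, not as a failure of the
  correction per se.
* On the C-shape study, compensation moves every figure of merit in the
  right direction (DVH-RMSE 39.3 to 28.2 percentage points, 5%/5 mm gamma
  pass 7.9% to 20.2%, SSIM 0.019 to 0.035). The absolute numbers are far
  from the measured study's (6.92 to 4.85; 56.86% to 78.24%) because the
  twin's C images are face- and edge-dominated — a planar array only
  receives wavefronts whose normals point at it, and the in-plane walls of
  the C radiate sideways — whereas the measured images are much closer to
  filled dose maps.
* The simulated sensitivity map's DVH places 33% of the 15 x 15 x 25 cm
  volume above 0.5 relative amplitude, versus the 80% the reference maps
  (measured and simulated) show. No width of the sinc angular response
  reproduces both the 15 cm focal zone and the 80% fraction: the first
  demands a narrow acceptance, the second a broad one. The real array's
  angular response evidently has a shape (narrow mainlobe plus substantial
  wide-angle response, or strong range dependence) that the stated geometry
  does not determine, and we chose to calibrate the focal zone — the feature
  the compensation mechanism depends on — and report the DVH fraction as we
  compute it. The 2° sweep step of the reduced-resolution protocol also
  scallops the map between rays (the focused beamwidth is about 2° FWHM),
  further lowering the fraction relative to the converged 0.5° sweep.

What passing tests do and do not show: the suite verifies the pipeline's
internal physics (superposition, delays, 1/r, envelope recovery, oracle
equivalence for gamma/SSIM/DVH) and the direction and rough magnitude of the
compensation benefit on a noiseless homogeneous twin. It does not establish
quantitative agreement with measured data — heterogeneous media, acoustic
attenuation, element-to-element sensitivity spread, and the real angular
response are all outside the model.

## Numerical choices

* Half-open angular grids ([0°, 180°)): matches the stated 360 x 360 event
  count; a closed interval would give 361 angles per axis.
* Event pruning window: 1.5° (about 1.5 beamwidths), widened to one step for
  coarse plans; `window_deg = Inf` recovers the exhaustive sweep exactly.
* Reciprocal floor 0.05; floored voxels counted and logged.
* Delay interpolation linear; out-of-range delays zero the voxel with a
  count.
* Gamma search radius 3 x DTA, 1/3-voxel steps, candidates sorted by
  distance with early exit; the grid spacing must not exceed the DTA.
* DVH on 101 levels; normalized (a.u.) volumes use relative dose.
* Trilinear densification with edge clamping.
* Every stochastic operation takes an explicit seed; the driver seeds once
  from the configuration and reports are byte-reproducible.
* C-shape coordinates are symmetrized exactly about the volume center so
  the mask's mirror symmetry holds to the last bit even when a gap edge
  crosses voxel diagonals.

## Known limitations

Homogeneous, lossless, single-sound-speed medium; no element-to-element
sensitivity spread (the measured array has a known low-sensitivity region on
one side, not modelled); transmit-receive reciprocity assumed; narrowband
directivity evaluated at the center frequency; point-sensitivity
compensation only (no deconvolution of the spatially varying PSF); no
DICOM-RT interfaces — dose volumes are synthetic or NIfTI.
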
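# irai — sensitivity-compensated quantitative radiation acoustic imaging

Ionizing radiation acoustic imaging (iRAI) maps the dose delivered by pulsed
x-ray beams in real time: each microsecond accelerator pulse heats the
deposited-dose region, launching pressure transients that a 2D matrix array
transducer (MAT) receives and a delay-and-sum beamformer turns into a 3D
image. Image amplitude, however, confounds dose with the array's strongly
position-dependent detection sensitivity, so uncorrected iRAI cannot be
quantitative. This package implements and evaluates the correction: simulate
the array's volumetric detection sensitivity, invert it into voxel-wise
correction factors, and multiply reconstructed volumes by them.

It is a simulation and analysis toolkit for medical-physics researchers:
everything (transducer, phantoms, beams, treatment plan, channel data) is
synthetic and generated in code.

## The model in brief

* **Array**: 32 × 32 elements, 3.45 mm square, 0.2 mm kerf (3.65 mm pitch,
  11.66 cm aperture), 0.35 MHz center frequency, 50% fractional bandwidth.
* **Sensitivity map**: a dynamic-focusing sweep over steering angles
  (azimuth × elevation on the half-open [0°, 180°) grid; 0.5° steps give
  129 600 events). With focal delays tracking range, the on-ray field value
  is `S(x) = Σᵢ Dᵢ(x)/rᵢ(x)` (element directivity over spherical spreading);
  the map is the voxel-wise maximum over events, normalized to 1. A virtual
  point-source protocol (simulate point source → reconstruct → record image
  maximum) reproduces the physical characterization and agrees with the
  sweep.
* **Correction**: `C(x) = 1 / max(S(x), ε)`, ε = 0.05.
* **Forward model**: initial pressure `p₀ = Γ ρ D` (Gy = J/kg), exact
  retarded-potential superposition in the homogeneous oil phantom
  (c = 1445 m/s, ρ = 920 kg/m³), convolved with the derivative of the 4 µs
  x-ray pulse envelope.
* **Reconstruction**: complex (analytic-signal) delay-and-sum with envelope
  detection; compensation is voxel-wise multiplication by `C`.
* **Evaluation**: cumulative DVH and DVH-RMSE, 3D global gamma (5%/5 mm,
  10% low-dose threshold), Gaussian-windowed SSIM, 80% isodose contours,
  region-mean amplitudes, midline profiles.

## Worked example

Reproduce the lateral beam study — seven 1 × 1 cm beams at 11 cm depth,
spaced 2 cm — and check that compensation flattens the position dependence:

```r
library(irai)
report <- run_experiment(study = "lateral")
round(report$region_mean_pre, 3)
#> 0.376 0.695 0.921 1.000 0.921 0.695 0.376
round(report$region_mean_post, 3)
#> 0.803 0.987 0.999 1.000 0.999 0.987 0.803
c(report$cv_pre, report$cv_post)
#> 0.361 0.100
```

Before compensation the region-mean amplitude of identical beams falls to
0.38 of the central value at ±6 cm offsets — pure detection-sensitivity
shading, since the beams are identical. After voxel-wise compensation the
means agree within about 20% everywhere and the coefficient of variation
drops 3.6-fold. The depth study (`study = "depth"`) shows the complementary
signature (amplitudes rising with depth toward the array's ~15 cm focal
zone, CV 0.43 → 0.14), and `study = "cshape"` runs a C-shaped treatment plan
and reports pre/post DVH-RMSE, gamma pass rates and SSIM against the plan.

Lower-level building blocks are exported individually
(`simulate_sensitivity_map()`, `virtual_point_source_map()`,
`correction_factors()`, `propagate()`, `das_reconstruct()`, `compensate()`,
`gamma_index()`, `dvh()`, ...), and a thin command-line front end over them
ships in `inst/cli/irai.R`. The methods vignette
(`vignettes/sensitivity-compensated-irai.Rmd`) documents the model,
its assumptions, the calibrated element angular response, and the known
limits of voxel-wise compensation for extended dose regions.

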
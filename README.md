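# backres

**Minimal sampling and camera resolution for 3D back-surface topography.**

Optical 3D scanners — from industrial structured-light systems to low-cost
consumer depth cameras — are used to screen for adolescent idiopathic
scoliosis by analysing the shape and left–right asymmetry of the back. Before
trusting any such device, one must know whether it samples the surface finely
enough to capture the deformity at all. `backres` is for researchers and
engineers selecting or validating a 3D capture setup: it determines the
minimal spatial sampling interval (mm between surface samples) and the
corresponding minimal camera resolution (pixels) required to capture the 3D
shape of the human back.

## Method

Given ground-truth point clouds of backs (or the built-in band-limited
synthetic generator), the package runs three complementary analyses:

1. **Spectral analysis.** Each back is cut into horizontal slices,
   regularized to uniform profiles *z = f(x)*, and Fourier-transformed. The
   frequency *f*<sub>max</sub> bounding the cumulative spectral power gives,
   by the Nyquist theorem with a practical oversampling factor *k*, a
   sampling requirement
   *f*<sub>s</sub> = 2·*k*·*f*<sub>max</sub>, i.e. one sample every
   *d* = 1/*f*<sub>s</sub> mm.
2. **Shape-degradation sweep.** Surfaces are degraded by a zero-phase
   Butterworth low-pass of decreasing cutoff *f*<sub>c</sub> (plus optional
   downsampling, depth quantization and noise), scored by the mean absolute
   depth error e(*f*<sub>c</sub>) against the unfiltered surface. The *slope
   break-point* — the smallest cutoff whose error stays within a chosen
   tolerance — brackets the frequency band that must be preserved.
3. **Symmetry-line sensitivity.** The same sweep scored by the lateral
   displacement (mm) of the back's symmetry line, the line of minimal mirror
   asymmetry that ideally overlies the spinous processes.

The break-point band (*f*<sub>c,low</sub>, *f*<sub>c,high</sub>) then
translates into the sampling-interval band *d* = 1/(2·*k*·*f*<sub>c</sub>)
and into camera pixel counts per axis,

> *r*<sub>c,min,x</sub> = *W*<sub>ROI</sub> / (*c*<sub>f</sub> · *d*),  
> *r*<sub>c,min,y</sub> = *H*<sub>ROI</sub> / (*c*<sub>f</sub> · *d*),

with region of interest *W*<sub>ROI</sub> × *H*<sub>ROI</sub> (default
454 mm × 516 mm, 95th-percentile male back) and fill factor *c*<sub>f</sub>
(default 0.67).

## Worked example

```r
library(backres)

cfg <- run_config(
  n_subjects    = 5,
  cohort_ranges = list(asymmetry_quadratic = c(0, 15),
                       amplitude_scale     = c(0.85, 1.15)),
  seed          = 1)
res <- run_pipeline(cfg, "backres-run")

res$shape_curve
#> ErrorCurve (shape_mae):
#>   fc = 0.07912 mm^-1 -> MAE = 0.0651 mm
#>   fc = 0.03956 mm^-1 -> MAE = 0.2342 mm
#>   fc = 0.01582 mm^-1 -> MAE = 0.6017 mm
#>   fc = 0.007912 mm^-1 -> MAE = 1.423 mm
res$breakpoint
#> Breakpoint: fc = 0.03956 mm^-1 (error 0.2342 mm <= tolerance 0.5 mm), band (0.01582, 0.03956) mm^-1
res$requirement
#> ResolutionRequirement
#>   breakpoint band : (0.01582, 0.03956) mm^-1, oversampling 5x (frequency factor 10x)
#>   sampling interval: 2.528 mm - 6.319 mm
#>   camera pixels    : 107 px - 268 px (x)  x  122 px - 305 px (y)
#>   ROI 454 mm x 516 mm, fill factor 0.67
```

Reading: on this synthetic cohort the error stays below the 0.5 mm tolerance
down to a cutoff of 0.0396 mm⁻¹, so with 5× oversampling one surface sample
every ≈ 2.5–6.3 mm suffices, which a camera with ≈ 107–268 × 122–305 pixels
on the back region already delivers. Translating an externally determined
band directly:

```r
requirement_report(c(0.02, 0.05), oversampling = 5)
#> ResolutionRequirement
#>   breakpoint band : (0.02, 0.05) mm^-1, oversampling 5x (frequency factor 10x)
#>   sampling interval: 2 mm - 5 mm
#>   camera pixels    : 136 px - 339 px (x)  x  154 px - 385 px (y)
#>   ROI 454 mm x 516 mm, fill factor 0.67
```

i.e. one sample every 2–5 mm and a minimal camera resolution of
136–339 px × 154–385 px — comfortably met by any 640 × 480 depth camera.

A thin command-line interface over the same functions lives in
`inst/cli/backres.R` (subcommands `simulate`, `spectrum`, `sweep-shape`,
`sweep-symmetry`, `resolution`, `run`), and
`inst/scripts/validate_deposited.R` reruns the analyses on a user-supplied
directory of real ground-truth captures.

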
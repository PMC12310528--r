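# panorama

Label-free detection, counting and sizing of single nanoparticles —
small extracellular vesicles (sEVs) in particular — from ratiometric
plasmonic transmission microscopy.

## The measurement

An arrayed gold-nanodisk sensor supports a localized surface plasmon
resonance (LSPR) whose peak wavelength shifts with the local refractive
index at a bulk sensitivity *S* (nm/RIU). When a vesicle binds to the
antibody-functionalized surface, the local index rises, the resonance
red-shifts, and — because the sample is illuminated through a narrow
bandpass filter sitting on the short-wavelength shoulder of the
resonance — extinction inside the band drops and transmission at the
particle's position increases. The particle appears as a bright
diffraction-limited spot in the ratio of a sample image to a
particle-free background image.

The pipeline implements, per frame:

1. **Registration** — integer-pixel alignment of sample to background by
   exhaustive normalized cross-correlation.
2. **Ratiometric image** — per-pixel intensity ratio IR = sample /
   background; IR > 1 marks enhanced transmission.
3. **Statistical threshold** — IR = 1 + 3σ + 0.005, where σ is the
   robust standard deviation of background IR values and 0.005 an
   absolute safety margin.
4. **Particle calling** — 8-connected components of supra-threshold
   pixels (≥ 2 px); per-particle contrast = (IR<sub>peak</sub> − 1) × 100%.
5. **Sizing** — the empirical quadratic calibration
   *Y* = 0.153 *X*² + 7.096 *X* + 20.211 (X contrast in %, Y diameter in
   nm), with classification into sEVs (contrast < 18% or diameter
   < 200 nm) versus large EVs.
6. **Time-lapse aggregation** — cumulative binding counts across
   before-wash (BW) frames by centroid matching, a before/after-wash
   (AW) retention comparison, and replicate mean ± sd across devices.

A seeded synthetic generator renders ground-truthed acquisition series —
LSPR-consistent multiplicative particle footprints under a Gaussian PSF,
fixed-pattern background texture, camera noise matched to 30 ms × 100
frame averaging, optional rigid drift, and exponential binding over a
60-min push-pull schedule with a wash step — so every stage of the
pipeline is testable against known truth without any external data.

## Worked example

Simulate a 256 × 256-px sub-field (41.6 µm × 41.6 µm) with 200 candidate
particles under the standard schedule, then run the full pipeline:

```r
library(panorama)

cfg <- default_config(
  fov        = list(width = 41.6, height = 41.6),  # 256 x 256 px
  simulation = list(n_candidates = 200),
  seed       = 42L)

fov      <- field_of_view(41.6, 41.6, 0.1625)
sched    <- flow_schedule()                 # 20 uL, 1.5 uL/min push-pull
particles <- simulate_binding(200, 0.023, sched, wash_retention = 0.575,
                              fov = fov, seed = 42)
series   <- make_series(fov, particles, imaging_config(), sched, seed = 42)
report   <- analyze_series(series, cfg)
report
#> Run report (sigma 0.00171, threshold 1.01013)
#>   time_min n_raw n_new cumulative
#> 1       20    64    64         64
#> 2       40   102    38        102
#> 3       60   134    32        134
#> After wash: 88 of 134 retained (fraction 0.657)
report$bw_summary
#> Detections: 134
#> Contrast: 8.52 +/- 3.42 %
#> Diameter: 93.50 +/- 34.24 nm
```

The estimated background noise σ ≈ 0.0017 puts the detection threshold
at ≈ 1.010 — a total excursion of about 1% contrast. Binding accumulates
monotonically across the three 20-min imaging intervals; the wash frame
retains 88 of the 134 particles present at 60 min. The mean detected
contrast of 8.5% corresponds, through the calibration, to a mean
diameter near 94 nm — the typical exosome scale:

```r
contrast_to_diameter(sizing_calibration(), 9.1)
#> [1] 97.45455
```

The same pipeline runs from the shell on TIFF stacks via the bundled
CLI (`simulate`, `detect`, `report` subcommands):

```sh
cli=$(Rscript -e 'cat(system.file("cli/panorama.R", package = "panorama"))')
Rscript "$cli" simulate --config run.yaml --out simdir
Rscript "$cli" detect --background simdir/background.tif --out detdir \
        --aw simdir/aw.tif simdir/frame_0*min.tif
```

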
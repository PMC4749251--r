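# octintensity

Quantitative analysis of retinal layer **optical intensity** (reflectivity) in
3-D macular spectral-domain OCT volumes.

Most OCT analysis measures layer *thickness*. The optical intensity of each
layer — how strongly its tissue backscatters — carries independent information:
the nerve fiber layer dims with axonal loss, the photoreceptor bands report on
outer-segment integrity, and overall signal strength varies with media opacity
and device signal quality. Establishing what *normal* intensity looks like, per
layer and per macular region, requires a reproducible measurement chain:
denoise the volume, segment the intraretinal surfaces, locate the fovea, lay
down the standard ETDRS sector chart, average intensity per layer and sector,
and run cohort-level statistics (repeatability ICCs, covariate correlations,
stepwise regression on age and image quality). This package implements that
chain end to end, together with a fully parameterized synthetic-data generator
with known ground truth so every stage can be validated quantitatively.

## What is implemented

* **Synthetic data** — `generate_phantom()` renders an 8-layer macular phantom
  (11 surfaces, foveal pit, per-layer central and nasal–temporal intensity
  modulation, gamma speckle, axial point-spread blur) and returns the exact
  ground-truth surfaces. `generate_rescan_pair()` adds between-visit jitter for
  repeatability studies; `generate_cohort()` draws subject tables from a
  configurable covariate/effect model.
* **I/O** — 16-bit multi-page TIFF or NIfTI-1 volumes with a JSON sidecar
  (spacing, laterality, image quality); CSV tables and surface files.
* **Preprocessing** — `denoise_cad()`, curvature anisotropic diffusion
  (modified-curvature diffusion equation) applied per B-scan.
* **Segmentation** — `segment_retina()` finds all 11 surfaces by optimal
  surface detection: each surface is the global minimum of a vertex-weighted
  graph problem under hard smoothness constraints, solved exactly as a minimum
  closed set via a maximum-flow/minimum-cut computation implemented in C++
  (`src/maxflow.cpp`). Interior surfaces are initialized from the axial
  intensity profile and refined in flattened sub-bands; `qc_surfaces()` flags
  implausible results.
* **ETDRS mapping** — `locate_fovea()` (deepest point of the inner limiting
  membrane) and `build_etdrs_masks()` (1/3/6-mm rings, quadrants with
  laterality-aware nasal/temporal labels).
* **Intensity metrics** — `layer_sector_intensity()`: mean/SD of intensity for
  8 layers × 9 ETDRS sectors (+ whole-chart and whole-scan rows), computed in
  closed form from cumulative sums.
* **Statistics** — `icc_two_operator()` (two-way ICCs from ANOVA mean
  squares), `correlation_screen()`, `compare_groups()`, `stepwise_ols()`
  (partial-F forward/backward selection with standardized coefficients),
  `age_group_summary()`.
* **Pipeline** — `run_pipeline()` orchestrates simulate-or-read → denoise →
  segment → QC → ETDRS → intensity → statistics from a single YAML/JSON
  config, deterministically under a fixed seed.

## Worked example

```r
library(octintensity)

# simulate one macular volume with ground truth
spec <- phantom_spec(dims = c(128L, 32L, 256L))
ph <- generate_phantom(spec, seed = 42)
ph$volume
#> <oct_volume> 128 x 32 x 256 voxels (OD), 0.047 x 0.188 mm lateral spacing, imageQ 58.0

# segment the 11 retinal surfaces and compare to ground truth
surf <- segment_retina(ph$volume)
round(vapply(1:11, function(i) mean(abs(surf$z[[i]] - ph$truth$z[[i]])), 0), 2)
#>  [1] 0.08 0.18 0.33 0.29 0.52 0.11 0.03 0.07 0.28 0.28 0.00

qc_surfaces(surf)$pass
#> [1] TRUE

# fovea, ETDRS chart, layer-by-sector intensity
ctr <- locate_fovea(surf)
round(ctr, 1)
#>    x    y
#> 64.0 16.5
grid <- build_etdrs_masks(ctr, ph$volume$laterality,
                          dim(ph$volume$voxels)[1:2], ph$volume$spacing)
tab <- layer_sector_intensity(ph$volume, surf, grid)
subset(tab, sector %in% c("Cen", "Nout", "Tout", "WholeETDRS") &
            layer %in% c("RNFL", "GCL", "RPE"))[, 1:4]
#>    layer     sector  mean_au    sd_au
#> 1   RNFL        Cen 26208.53 3783.225
#> 7   RNFL       Nout 32407.89 4409.627
#> 9   RNFL       Tout 30557.71 4169.430
#> 10  RNFL WholeETDRS 31050.59 4525.082
#> 12   GCL        Cen 25484.82 3057.670
#> 18   GCL       Nout 26800.51 3228.375
#> 20   GCL       Tout 26548.34 3179.681
#> 21   GCL WholeETDRS 26574.60 3201.084
#> 78   RPE        Cen 35371.29 4534.546
#> 84   RPE       Nout 34443.22 4475.333
#> 86   RPE       Tout 34968.99 4484.305
#> 87   RPE WholeETDRS 34794.27 4520.243
```

The recovered profile shows the encoded structure: the nerve fiber layer is
centrally depressed and nasally brighter, while the retinal pigment epithelium
is centrally elevated and temporally brighter. (A warning notes that the 6-mm
chart touches the scan border; sectors are clipped accordingly.)

```r
# cohort statistics: stepwise regression on a simulated 231-subject cohort
coh <- generate_cohort(cohort_model(), 231, seed = 7)
fit <- stepwise_ols(coh, "RNFL", c("age", "imageQ"))
fit$selected
#> [1] "imageQ" "age"
round(fit$beta, 3)
#> imageQ    age
#>  0.604 -0.292
```

A full multi-volume run, including QC exclusion logs, sector-comparison
t-tests, rescan ICCs, correlation screens, stepwise models and age-decade
summaries, is one call:

```r
cfg <- pipeline_config()
cfg$seed <- 1
cfg$out_dir <- "results/demo"
cfg$simulate$n_volumes <- 5L
run_pipeline(cfg)
```

## Documentation

Every exported function carries full roxygen documentation. The methods
vignette (`vignettes/oct-intensity-methods.Rmd`) describes the synthetic-data
model, the graph construction and solver, the numerical choices and their
rationale, and the limitations of the approach.
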
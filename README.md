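# sptfa

Single-protein tracking and super-resolution analysis of focal-adhesion
proteins, in R.

## The problem

Focal adhesions (FAs) are integrin-based structures that couple the
extracellular matrix to the actin cytoskeleton. How adaptor proteins such as
kindlin and talin reach and activate integrins can be read out from live-cell
single-molecule experiments: sptPALM trajectories reveal whether a molecule
diffuses freely along the membrane, is transiently confined, or is immobilized
on an adhesion; kymographs of super-resolved time-lapses measure how long
immobilizations last and whether immobilized molecules move rearward with
actin flow; paired TIRF/epifluorescence photometry quantifies membrane
recruitment; and 3D localization microscopy places each molecule at an
absolute height above the coverslip, resolving the nanoscale layering of the
adhesion.

`sptfa` implements that full analysis chain for localization/track tables
(delimited text) plus a synthetic-data generator that provides ground truth
for every stage, so each analysis step is validated against data whose answer
is known.

## The statistics at the core

For a trajectory of N positions sampled every Δt = 20 ms (50 Hz), the mean
squared displacement at lag n·Δt is

    MSD(n·Δt) = (1 / (N − n)) Σ_{i=1..N−n} (x_{i+n} − x_i)² + (y_{i+n} − y_i)²

computed gap-aware (pairs matched by frame-index difference). Trajectories
shorter than 13 points (260 ms) are excluded. The diffusion coefficient D is
the slope of the affine (free-intercept) regression through the n = 1..4 MSD
values, divided by 4 (MSD = 4Dt in 2D); the intercept absorbs the 4σ²
localization-noise offset. A molecule is **immobile** when

    D < FWHM² / (4 · 4 · Δt) = (0.059 µm)² / (4 · 4 · 0.02 s) ≈ 0.011 µm²/s,

i.e. it explored less area than the spatial resolution during the slope
window. Mobile trajectories are fitted (weighted by per-lag pair counts, over
80% of the lags, minimum 10 points = 200 ms) with the confined-diffusion
model

    MSD(t) = (4 r_conf² / 3) (1 − exp(−t/τ)),   τ = r_conf² / (3 D_conf)

and split into **confined** (τ < 100 ms, half the minimum fit duration) and
**free** (τ ≥ 100 ms). Per-cell mode fractions and log₁₀(D) distributions are
averaged across cells with SEM error bars. The resolution itself is estimated
from ≥50-frame immobile clouds as FWHM = 2.3·s_xy, with s_xy the fitted 2D
Gaussian sigma.

The other modules implement: 25-frame merging into 0.5 s super-frames and
kymograph extraction along an FA-tangential polyline with automated streak
detection (duration, signed rearward speed, fraction ≥ 2 nm/s); the
membrane-fraction estimator F_membrane = (Fluo_TIRF/BG_TIRF) /
(Fluo_epi/BG_epi); FA enrichment = (mean inside FA − background) /
(mean outside FA − background); and axial profiling — FFT cross-correlation
lateral drift correction, 15 nm mean-z maps (z ≤ 150 nm, 5×5 smoothing), and
per-region z histograms with Gaussian-fitted peaks z_peak (box statistics on
z ≤ 200 nm).

## Worked example

```r
library(sptfa)

cfg <- pipeline_config(sim = sim_config(n_frames = 50),
                       n_cells = 3, n_tracks = 120, seed = 42, verbosity = 0)
res <- run_full(cfg)

p <- res$summary$pooled$outside_fa
round(p$mean_fractions, 3)
#> immobile confined     free
#>    0.349    0.318    0.333
round(p$sem_fractions, 3)
#> 0.043 0.016 0.043
head(res$classifications[, c("id", "region", "mode", "D", "tau")], 3)
#>      id     region     mode            D   tau
#> 1 t0001 outside_fa     free 0.2067802650 100.0
#> 2 t0002 outside_fa immobile 0.0006240943    NA
#> 3 t0003 outside_fa     free 0.1737569281 100.0
```

The simulator drew equal thirds of immobile, confined and free trajectories;
the recovered pooled fractions (0.349, 0.318, 0.333) match within the SEM
across the three simulated cells. Per-trajectory rows report the
initial-slope D in µm²/s (t0002 is two orders of magnitude below the 0.011
µm²/s immobility threshold) and the confinement time constant τ in seconds
(τ pinned at its 100 s bound means the plateau was never reached — free
diffusion).

Classifying one synthetic confined trajectory directly:

```r
tr <- simulate_trajectory("confined",
        sim_config(n_frames = 200, disc_radius = 0.15, D_conf = 0.1), seed = 5)
classify(tr)
#> <motion: confined, D = 0.03188 um^2/s, tau = 0.0665 s, r_conf = 0.135 um>
```

The fitted confinement radius 0.135 µm approximates (√3/2)·R = 0.130 µm, the
plateau value implied by a 0.15 µm reflecting disc.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "sptfa", package = "sptfa"))')
Rscript "$CLI" simulate --seed 3 --out demo/
Rscript "$CLI" classify --locs demo/localizations.csv --masks demo/masks.json --out demo/
Rscript "$CLI" compare --a 1,2,3 --b 4,5,6
# p = 0.1
```

Subcommands: `simulate`, `classify`, `kymo`, `enrich`, `zprofile`, `run-all`,
`compare`; `--config` accepts a YAML or JSON pipeline configuration.

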
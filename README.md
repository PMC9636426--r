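# burststage

An R analysis workflow for quantifying transcriptional bursting of
nascent-transcription spot traces across erythroid differentiation.
It is written for groups doing live-cell imaging of tagged genes (e.g.
PP7/MS2 stem-loop arrays bound by a fluorescent coat protein) in
differentiating erythroid cells, who need to turn per-cell spot-intensity
time series and CD71/Ter119 surface-marker measurements into staged,
per-cell burst statistics and behaviour classes.

## What it computes

**Staging.** Each cell's raw markers are compressed by
x′ = asinh(x/cofactor) and projected onto a family of marker-trajectory
curves discretised into 10,000 equal-arc-length points; the cell's
differentiation position is the arc-length fraction of the nearest point,
binned into stages DS1–DS6. Two datasets' axes can be aligned by the
fluctuations of cell size along the axis.

**Burst metrics.** A trace is a piecewise-linear interpolant; ON
intervals against a threshold (default 350 a.u.) are solved exactly. Per
cell: ON fraction (ON time / imaging window), complete-burst durations
and sizes (area above threshold; bursts touching the window edges are
incomplete), and transcriptional output (summed area over all
intervals). Frame-interval choice is guided by subsampling RMSE,
`sqrt(sum((y_sub − y_raw)^2)/n)` over the raw time grid.

**Variability.** Per-cell Fano factor (variance/mean of the intensity
series), per-stage Fano-versus-mean OLS slopes and their ratio to the
pooled slope, bootstrap percentile CIs for stage medians (n = 31 drawn
with replacement, 10,000 resamples), and two-sided Mann–Whitney stage
contrasts.

**Behaviour classification.** Robust LOWESS of output on ON duration;
the inflection of its gradient splits High-ON from Low-ON cells; a
quadratic through the Low-ON curve extrapolates basal output; each
cell's *basal amplitude deviation score* is its residual from that
quadratic divided by its ON duration, thresholded at the Low-ON
median + 1 SD. Classes: basal, high-ON/high-amplitude,
low-ON/high-amplitude.

**Synthetic data.** A first-class module simulates telegraph-promoter
traces (exact continuous-time switching, frame-averaged occupancy),
marker trajectories with lognormal noise, cell sizes, and 3D image
stacks (bright cytoplasm, GFP-depleted nucleus, Gaussian nuclear spot)
with ground-truth masks — so the whole chain is testable without
external data. An image-quantification module (two-step k-means
segmentation, ovoid spot measurement with nuclear background
subtraction, iteratively smoothed marker background, central-slice cell
size) closes the loop from images to traces.

## Worked example

The numbered drivers under `analysis/` run the full study on the default
synthetic population and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/03_stage.R
Rscript analysis/04_bursts.R
Rscript analysis/06_classify.R
```

Output from those runs (600 cells, default seed):

```
staged 600 cells; Spearman(true, recovered position) = 0.994
at ON threshold 350: median ON fraction 0.57, median output 6735 a.u.min, 1503 complete bursts
complete bursts: median duration 5.8 min, median size 986 a.u.min
duration-output inflection at 50.6 min (84% of the imaging window)
96.0% of cells recover their generating regime
stage ranking of median ON fraction invariant across thresholds 250-450: TRUE
```

The Spearman correlation says marker noise at CV 0.2 barely disturbs the
recovered differentiation ordering; the inflection near 84% of the
window separates nearly-continuously-active cells from the rest; and the
classifier's 96% regime recovery means the deviation-score threshold
cleanly re-identifies the three generating behaviours. In the same runs,
median ON fraction per stage peaks mid-differentiation (≈0.43 at DS1,
≈0.81 at DS3, ≈0.30 at DS6) and behaviour-class proportions stay >70%
basal at every stage with high-ON/high-amplitude cells enriched at
DS3–4 — the qualitative structure the generator is designed to emulate.

Equivalent programmatic entry point:

```r
library(burststage)
bundle <- run_pipeline(analysis_config(seed = 1), outdir = "results/bundle")
bundle$stage_stats
generate_report(bundle, "results/figures")
```

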
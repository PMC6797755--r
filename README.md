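# wntnoise

Quantification of spatiotemporal noise in morphogen-reporter gradients.

During zebrafish anterior-posterior (AP) axis formation, Wnt/β-catenin
signalling forms an activity gradient — high posterior, low anterior.
Single cells whose reporter activity deviates strongly from their
neighbours ("unfit" cells) appear spontaneously, inject local noise into
the gradient, and are removed by apoptosis. `wntnoise` provides the
quantitative toolbox for studying this process from single-channel
time-lapse reporter movies, with a synthetic-scene generator so that
every stage is testable end to end without any external imaging data.

## What it computes

**Noise-pixel classifier** (`detect_noise()`). Per frame, pixel *p* is
compared with the statistic *s(p)* of its masked neighbours (default:
8-connected ring mean): High iff *I(p) > 2·s(p)*, Low iff
*I(p) < s(p)/2* (strict). Per pixel, maximal same-class runs become
noise events iff they last ≥ 2 frames **and** strictly longer than
6 minutes; single-frame excursions are excluded as detector/cosmic-ray
transients and counted separately. Output: an event table
(x, y, class, frame span, peak fold) and a per-frame time course of
High/Low noise-pixel counts.

**Gradient profiling** (`partition_regions()`, `sample_intensity()`,
`gradient_shape()`, `smoothness_index()`). Evenly divided regions along
the AP axis, sampled intensity summaries (mean ± SEM), monotonicity and
posterior/anterior ratio, and a median-log-fold smoothness index.

**Spatial cell statistics** (`bin_frequencies()`, `nc_ratio()`,
`summarize_values()`, `fisher_exact_2x2()`). Per-embryo AP-binned
marker-positive frequencies, nuclear/cytoplasmic ratios, box-plot
summaries, and a two-sided exact 2×2 test (minimum-likelihood
hypergeometric summation).

**Expression gate** (`gate_de()`, `annotate_gate()`). From two DE
contrasts (mosaic vs uninjected, ubiquitous vs uninjected), extracts
genes significant (FDR < 0.1) only in the mosaic contrast, split by
direction, and annotates them against supplied gene panels.

**Synthetic scenes** (`sim_config()`, `simulate_scene()`,
`make_de_table()`, `make_cell_table()`). Seeded, bit-reproducible movies
with a smooth AP gradient, planted persistent outlier cells (Poisson
arrivals, geometric apoptotic lifetimes; rate 0 = apoptosis inhibited),
single-frame spikes and detector noise — plus ground-truth labels for
every planted feature.

## Worked example

```r
library(wntnoise)

cfg   <- sim_config(seed = 7)       # 100x100 px, 40 frames, 6.5 um, 3.5 min
scene <- simulate_scene(cfg)
scene$truth
#> ground_truth: 71 events (High 17, Low 13, Transient 41)

det <- detect_noise(scene$stack)
head(det$events[, c("x","y","event_class","start_frame","end_frame","peak_fold")])
#>    x  y event_class start_frame end_frame peak_fold
#> 1 12 27         Low           9        10 0.2908932
#> 2 89 75        High          10        11 3.2686424
#> 3 54 23        High          12        13 3.4849930
#> 4 13 22        High          13        19 3.7082503
#> 5 68 81         Low          13        14 0.3442605
#> 6 88  3        High          15        17 2.6614175
nrow(det$events); sum(det$transients_per_frame)
#> [1] 21
#> [1] 50
```

21 of the 30 planted outlier cells persisted long enough (≥ 2 frames,
> 6 min) to qualify as noise events and are recovered at their planted
positions and folds; all 41 planted spikes are excluded as transients,
along with the nine planted cells whose apoptotic elimination left them
visible for only a single frame.

```r
mask <- embryo_mask(scene$stack)[, , 1]
reg  <- partition_regions(mask, ap_spec(cfg$ap_axis, 3))
prof <- sample_intensity(scene$stack$data[, , 1], mask, reg, 12, seed = 7)
prof
#>   region     mean       sem n_samples
#> 1      1 10.19384 0.1468298        12
#> 2      2 20.83360 2.3507842        12
#> 3      3 57.88724 5.5669527        12
gradient_shape(prof)
#> $is_monotone_posterior_high
#> [1] TRUE
#> $posterior_anterior_ratio
#> [1] 5.67865

fisher_exact_2x2(matrix(c(12, 2, 3, 11), 2, 2))
#> [1] 0.001838142
```

The three-region profile recovers the planted exponential gradient
(posterior ≈ 5.7× anterior, means strictly increasing anterior →
posterior).

## Command line

The same stages are scriptable via the installed `exec/wntnoise`
Rscript: subcommands `simulate`, `detect`, `profile`, `spatial`,
`fisher`, `gate` and `run` (an end-to-end simulate → detect → profile
bundle with a checksummed manifest). Images travel as multi-page TIFF
with a JSON calibration sidecar; tables as versioned CSV with 0-based
pixel/frame indices.

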
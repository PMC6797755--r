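---
title: "Quantifying noise in morphogen-reporter gradients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying noise in morphogen-reporter gradients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wntnoise)
```

## The problem

During anterior-posterior (AP) axis formation in the early zebrafish
embryo, Wnt/β-catenin signalling forms an activity gradient: high at the
posterior end, low toward the anterior. Individual cells whose signalling
activity deviates strongly from their neighbours ("unfit" cells) appear
spontaneously, producing local noise in the gradient, and are removed by
apoptosis within minutes to hours. Quantifying this noise from time-lapse
reporter movies poses two separable problems:

1. deciding, per pixel and per frame, whether reporter intensity deviates
   multiplicatively from its local surroundings, and
2. deciding whether a deviation is *biological* (an unfit cell, which
   persists for several frames) or *instrumental* (a cosmic-ray or
   detector hit, which lasts exactly one frame).

`wntnoise` implements this two-stage classifier together with the
surrounding quantifications used in such studies — AP gradient profiles
over evenly divided regions, AP-binned marker-positive cell frequencies,
nuclear/cytoplasmic translocation ratios, an exact 2×2 test, and a gate
for mosaic-specific differential expression — plus a synthetic-scene
generator that makes every stage testable against planted ground truth.

## The noise-pixel classifier

Let $I_t(p)$ be the intensity of pixel $p$ in frame $t$, and $s_t(p)$ a
neighbourhood statistic (by default the mean over the 8-connected ring of
masked neighbours, excluding $p$ itself). The per-frame rule is

* **High**: $I_t(p) > \theta\, s_t(p)$,
* **Low**: $I_t(p) < s_t(p)/\theta$,
* **none** otherwise,

with fold threshold $\theta = 2$ and *strict* inequalities: a pixel at
exactly two-fold is not noise. Because only ratios enter, the
classification is invariant to global intensity rescaling (exposure,
gain), which the test suite checks byte-for-byte on the discrete event
fields.

The temporal stage collapses per-frame calls into maximal same-class runs
at fixed pixel coordinates. A run of $k$ frames is a **noise event** iff

* $k \ge$ `min_frames` (default 2), and
* $k \times$ `frame_interval_min` $>$ `min_duration_min` (default 6 min,
  strict).

Runs of length 1 failing the criteria are counted as **transients** —
single-frame excursions attributed to cosmic rays and detector noise —
and reported per frame but excluded from the event list, *whatever their
amplitude*. Runs of length ≥ 2 that fail only the duration test occupy a
middle ground the classification rule does not name; they are neither
events nor transients and are tallied separately (`n_short_runs`) so no
excursion is silently lost. With the default 3.5-min interval both
persistence criteria coincide (2 frames = 7 min > 6 min); at other
intervals both are enforced.

Duration is computed as $k \times$ interval, i.e. a 2-frame run is
credited the full time between and including both acquisitions. The
alternative convention $(k-1)\times$ interval would make a 2-frame run at
3.5 min span only 3.5 min and never satisfy the 6-min criterion, which
contradicts the intended "two frames, more than six minutes" reading; we
therefore use $k \times$ interval.

Other numerical choices:

* **Masking.** Analysis is restricted to an embryo mask: by default,
  pixels at or above the `mask_quantile` (0.1) intensity quantile of the
  frame and strictly positive, then a 3×3 morphological closing
  (`EBImage`). A supplied mask always wins; the automatic rule is a
  convenience for synthetic scenes and roughly background-free movies.
* **Boundaries.** Pixels use whatever masked neighbours exist; a pixel
  with none is unclassifiable (label none).
* **Degenerate ratios.** $s = 0$ with $I > 0$ classifies High with an
  infinite fold recorded — flagged rather than hidden, since it usually
  marks a mask defect. $s = 0 = I$ is none.
* **No registration.** Pixels are tracked at fixed coordinates. This
  mirrors the pixel-wise definition of the classifier and is the main
  simplification to remember when applying it to drifting embryos:
  motion splits a long-lived cell into shorter pixel runs.

Whether the neighbourhood should be the immediate ring or a wider window,
and whether intensities should be pre-filtered, are left as parameters
(`neighbourhood_radius_px`, `neighbour_stat`; filtering is out of scope)
rather than fixed, since the original desktop analysis pipeline does not
pin them down; the defaults are the most local, least processed choice.

## The synthetic-scene generator

`sim_config()` + `simulate_scene()` emulate the statistical structure the
classifier assumes, not the optics of any particular microscope:

* a smooth background gradient along a configurable AP axis —
  exponential $I(d) = P e^{-d/\lambda}$ floored at the anterior level,
  linear, or constant;
* **persistent outlier cells**: Poisson arrivals (`unfit_rate` per
  frame), rendered as discs of `cell_diameter_um` (10 μm; at the default
  6.5 μm pixel size a disc is a single pixel, matching the single-cell
  scale of the phenomenon), multiplying the background by a fold drawn
  uniformly from [`unfit_fold_min`, `unfit_fold_max`] (reciprocal for Low
  cells). Lifetimes are $1 + \min(\mathrm{Geom}(r), \text{cap}-1)$
  frames: the memoryless geometric is the simplest stand-in for apoptotic
  removal at per-frame hazard $r$ = `elimination_rate`, and $r = 0$
  encodes the apoptosis-inhibited condition (cells persist to the
  lifetime cap);
* **spikes**: Poisson single-frame, single-pixel excursions (a detector
  or cosmic-ray hit is sub-cellular);
* **detector noise**: multiplicative Gaussian (`noise_scale` fraction of
  local intensity) or Poisson shot noise (`noise_scale` photons per
  intensity unit), applied last.

Event centres are drawn uniformly but kept a minimum Chebyshev distance
apart (rejection sampling). This is a deliberate generator property: the
planted event list doubles as a test oracle, and separation guarantees
each planted event is individually attributable in the detection output.
At the default rates (≈ 20 cells and 50 spikes per 100×100×40 movie) the
rejection rate is negligible and arrival statistics stay Poisson to well
within the Monte-Carlo tolerances the tests check.

What the generator does **not** emulate — and what passing tests
therefore do not certify on real data: cell motion and tissue flows,
point-spread blur, photobleaching, embryo curvature, spatially
correlated background fluctuations, and overlapping unfit cells. The
defaults (100×100 px at 6.5 μm, 40 frames at 3.5 min, fold deviations
2.5–4× against a 2× threshold) describe a clean, well-sampled movie of
the kind the classifier was designed for.

All randomness flows from one master seed per configuration (event
drawing and detector noise use documented offsets of it), so a scene is
bit-reproducible from its `sim_config` alone; `ground_truth()` lets a
caller bypass the random generator entirely and plant an exact event
list.

## Gradient profiling

`partition_regions()` divides a mask into *n* contiguous bands of equal
coordinate span along the AP axis (geometric thirds for *n* = 3, as in
boundary-intensity profiles), not equal pixel counts; remainder columns
are absorbed anterior-first, and spans never differ by more than one
pixel. `sample_intensity()` draws a fixed number of sample points
(default 12 per region, the typical per-region cell count in such
profiles) without replacement from a caller-supplied sample mask — the
package deliberately does not segment membranes; sampling masks encode
whatever "intercellular areas" mean for a given experiment.
`gradient_shape()` reduces a profile to a monotonicity flag and the
posterior/anterior ratio; `smoothness_index()` is the median of
$|\log(I/s)|$ over masked pixels, a robust scalar that is exactly 0 for
locally smooth frames (the median ignores isolated outliers) and grows
with planted-event burden.

## Spatial statistics

`bin_frequencies()` computes marker-positive frequencies per embryo per
AP bin (default 5 bins — the bin count is not canonical and is exposed),
then averages across embryos: the embryo is the unit of analysis, so SEM
reflects inter-embryo variability, not pooled-cell counts. The AP extent
is the range occupied by population cells. `nc_ratio()` gives per-cell
nuclear/cytoplasmic mean-intensity ratios from disjoint masks.
`summarize_values()` provides box-plot statistics (type-7 linear
quantile interpolation). `fisher_exact_2x2()` implements the two-sided
exact test by minimum-likelihood summation of hypergeometric masses —
the convention of the common desktop tools, stated explicitly because
two-sided conventions differ — with a `fisher.test`-style relative
tolerance of $10^{-7}$ at the observed mass; *t* tests and ANOVA are
deliberately left to `stats`.

## The expression gate

`gate_de()` consumes per-gene statistics for two contrasts (mosaic vs
uninjected; ubiquitous vs uninjected) produced upstream by any DE engine,
and extracts genes significant (FDR < 0.1 by default) in the mosaic
contrast but **not** in the ubiquitous one, split by fold-change sign.
"Not in ubiquitous" is read minimally as "not significant at the same
threshold" — no effect-size criterion — and genes absent from a contrast
count as not significant there, since filtered DE tables routinely omit
untested genes. Both choices are parameters/documented rather than
hidden. `annotate_gate()` intersects the gated sets with supplied gene
panels (e.g. curated Smad-target lists), case-normalized.

## Validation strategy and problem sizes

Every stage is validated against planted ground truth on synthetic
scenes sized to run in seconds: 100×100 px × 40 frame movies for
detection (exact recovery of 20 planted events with 50 spikes excluded;
recall and precision 1.0 at 5% Gaussian noise over 10 seeds), 20 paired
80×80 scenes for the elimination-on/off comparison (assessed with an
exact sign test), exhaustive enumeration of all 2×2 tables with margins
≤ 10 against an independent binomial-coefficient oracle, 1000-seed
Poisson/hypergeometric Monte-Carlo checks, and 50 simulated embryos for
binned frequencies. `scripts/acceptance.R` re-runs exactly these
computations from scratch against the installed package and writes the
resulting numbers as JSON.

## Known limitations

* Fixed-coordinate tracking (no registration hook is enabled by
  default); drifting samples need pre-registration upstream.
* The automatic embryo mask is a quantile heuristic; real movies with
  structured background should supply a mask.
* The generator's outlier cells are static discs; lifetimes, not
  trajectories.
* The N/C ratio and membrane sampling assume caller-supplied masks;
  no segmentation is performed anywhere in the package.
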
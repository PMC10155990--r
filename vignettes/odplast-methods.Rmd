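---
title: "Measuring ocular dominance plasticity from two-photon calcium imaging: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring ocular dominance plasticity from two-photon calcium imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(odplast)
```

## The scientific problem

Closing one eye for a few days during the critical period of visual
development shifts the balance of eye-specific responsiveness in binocular
primary visual cortex (ocular dominance, OD, plasticity). Two-photon
calcium imaging with GCaMP6s makes it possible to measure this shift
neuron by neuron: which cells respond to the contralateral eye, the
ipsilateral eye, or both; how strongly; at which grating orientation and
spatial frequency (SF); and — with repeated imaging of the same field —
how each individual neuron's tuning changes after monocular deprivation
(MD).

`odplast` implements that measurement pipeline as reusable, tested
functions, together with a synthetic-data generator that produces
stimulus schedules, ground-truth neuron populations, and GCaMP6s-like
fluorescence traces so every stage can be validated by parameter recovery
without any raw recordings.

## Stimulus model

The stimulus battery is a random sequence of static sinusoidal gratings:
6 orientations (0–150° in 30° steps) x 8 SFs (0.028–0.48 cycles per
degree, cpd, in half-octave x1.5 steps) x 8 spatial phases (0–315° in 45°
steps), presented at 4 Hz while imaging at 15.5 Hz. An isoluminant grey
blank is drawn as a ninth level of the SF axis with the same probability
as each SF, so a 10-minute session contains 2,400 presentations spread
over 6 x 8 = 48 grating conditions plus the blank (realized per-condition
counts land around 30–56). Event `k` onsets at frame
`round(k * 15.5 / 4)`; the fractional 3.875-frame spacing means onsets
alternate between 3- and 4-frame gaps, as they do when stimulus
transitions are time-stamped to acquisition frames in hardware.

## Forward model of the synthetic data

Each simulated neuron carries a category (monocular contralateral C,
binocular B, monocular ipsilateral I, or nonresponsive NR), per-eye
response amplitudes, an orientation preference with a von Mises profile
on the doubled angle, `exp(kappa * (cos 2(theta - theta_pref) - 1))`, and
a log-Gaussian SF profile with width in octaves. For every presentation
the neuron emits Poisson spikes with mean
`a_eye * g_ori(theta) * g_sf(omega)`, placed at a lag drawn uniformly
from 4–9 frames after onset (the empirically time-locked window for this
indicator); baseline Poisson spikes are added everywhere; the spike train
is convolved with a single-exponential calcium kernel and Gaussian trace
noise is superimposed.

Defaults, chosen once as typical of critical-period L2/3 data and then
left alone:

| parameter | default | meaning |
|---|---|---|
| composition | 0.224 C, 0.185 B, 0.091 I, 0.5 NR | responsive part in the 294:243:120 ratio of a healthy critical-period field; half of somata nonresponsive |
| amplitude | lognormal, median 2 spikes | expected spikes per preferred presentation |
| `kappa_ori` | 2.5 | orientation tuning width ~44° FWHM |
| `sigma_sf` | 0.9 octaves | SF tuning width |
| `ipsi_ori_sd` | 30° | binocular-matching scatter; gives median delta-ori near 20° |
| `baseline_rate` | 0.02 spikes/frame | spontaneous activity |
| `noise_sd` | 0.08 dF/F | trace noise |
| `kernel_tau` | 1.6 s | GCaMP6s-like decay; amplitude 1 dF/F per spike |

The generator emulates contralateral bias, tuned subpopulations, and the
blank control. It does **not** emulate optics, motion artifacts,
neuropil contamination beyond a constant level, pupil state, or
correlated network activity — so passing recovery tests shows the
estimators invert this forward model, not that they are robust to every
pathology of real recordings.

## From fluorescence to inferred spikes

ROI traces are the mean over mask pixels minus the **median** over a
6-px neuropil annulus (median rather than mean so one bright pixel
cannot corrupt the trace; pixels of other ROIs are excluded, with a
nearest-free-pixel fallback). dF/F uses a rolling 60-s 20th-percentile
baseline (evaluated on a strided grid and interpolated), floored at a
small epsilon. The deposited analysis this package mirrors used a
published deconvolution routine whose details are not restated anywhere;
the spike-rate estimator here is therefore defined explicitly as a
smoothed, rectified, thresholded first difference (trailing 3-frame mean,
rectify at 0, threshold at 2 robust SDs of the differenced trace), behind
an interface so another deconvolver can be swapped in. Downstream
analysis uses only within-neuron relative inferred spike rate (ISR), so
the arbitrary scale is harmless.

## Responsiveness: reverse correlation and three criteria

For delays −2..18 frames around every onset, the mean ISR per condition
forms a delay x orientation x SF tensor. Cell z-scores are taken against
the mean and SD of the non-blank cells over the noise delays
{−2..0, 15..18}; the wording "before onset or after it" is read as
pooling both flanks into one noise sample. A neuron is visually
responsive for an eye when

1. its optimal delay (argmax of the per-delay best cell, smallest delay
   on ties) falls in frames 4–9;
2. its SNR — mean per-delay SD of the tensor across the grid in the 4–9
   window divided by the same statistic in the noise windows — exceeds
   the 75th percentile of the session's spontaneously active neurons
   (optimal delay outside 4–9); and
3. its spike ratio (SR), the percent of preferred-condition presentations
   with positive ISR at the optimal delay, exceeds the spontaneous 75th
   percentile.

Percentiles use linear interpolation between order statistics
(`quantile` type 7; spontaneous SNRs {1,2,3,4} give a threshold of
3.25). Classification is independent per eye. On pure-baseline
populations about 3–6% of neurons slip through all three criteria, well
under the 10% contract asserted in the tests.

## Tuning metrics

*Preferred stimulus*: grid argmax of mean ISR at the optimal delay,
blank excluded, lower orientation then lower SF index on ties.

*Preferred orientation*: half the argument of
`sum_n O_n * exp(i * 2 * pi * theta_n / 180)`, wrapped to [0, 180).
`O_n` is the z-score row at the preferred SF and optimal delay (the
slice is a design choice — the source text does not say which — and is
recorded in output metadata). Negative z entries are floored at zero
first: the formula is a weighted average and negative weights make it
ill-defined.

*Preferred SF*: `10^(sum_k Sf_k log10 omega_k / sum_k Sf_k)` after
clipping tails at 25% of the peak. "Tails" is implemented as walking
outward from the peak and zeroing entries once they fall below the clip
level, so interior dips above 25% are retained. `Sf_k` is the z column
at the preferred orientation.

*Widths*: full width at half maximum by linear interpolation; the
orientation axis is circular (capped at 180° when the curve never falls
below half max), the SF axis is linear in log2 (capped at the grid
span), with a flag whenever a cap fires.

*Per-SF significance*: Kruskal–Wallis across the 8 SF groups plus blank,
then Dunn's rank-sum z comparison of each SF against blank with the
corrected P multiplied by the 8 comparisons; significant means corrected
P < 0.01 with the SF's mean rank above the blank's. Dunn's post hoc is
implemented in-package (standard tie-corrected form) because no
installed package provides it.

## Ocular dominance and binocular matching

ODI = (C − I)/(C + I) on each eye's **own** preferred-stimulus dF/F
(baseline-corrected mean at onset + optimal delay); monocular neurons
are pinned to +1 (C) and −1 (I). Per mouse, mean ODI averages neuronal
ODIs; summed ODI first sums each eye's dF/F over that eye's responsive
neurons, weighting by response strength. Binocular matching is the
absolute circular difference of the two eyes' preferred orientations on
the 180° cycle (0–90°).

## MD as a transition model

Deprivation is modeled as a 4x4 stochastic matrix over {C, B, I, NR}
applied to the ground-truth population, plus amplitude rescaling
(`amp_scale_C = 0.65`, `amp_scale_I = 1`: deprived-eye depression,
nondeprived eye untouched). The default matrix is calibrated from the
printed longitudinal flow counts of the study this package models —
B-row 46/102/62/33 of 243, C→B 87 of 294, I→B 36 of 120, NR→B 21 — with
the free cells chosen so the post-MD marginals reproduce the collapse of
the C:I ratio to ~1 (198 vs 194 responsive neurons) given 294/243/120
responsive plus ~656 nonresponsive at baseline. A matching-dependent
rule tilts the B→I vs B→C split by 0.004 per degree of pre-MD mismatch
below/above 30°, so binocular neurons that were better matched
preferentially lose the deprived eye; with the 30° matching scatter this
lands the B→I median near 15° and the B→C median near 29°. Newly
binocular neurons draw their second-eye preference with a wider 40°
scatter (worse matching than developmentally binocular neurons).

## Longitudinal tracking

Masks from the two sessions are compared in the same pixel frame (no
registration, as in the experiment): overlap is |A∩B| / min(|A|,|B|)
(denominator a design choice; union/Jaccard is available by flag),
matching is greedy and one-to-one, and ≥50% overlap (inclusive) defines
the same neuron. The analysis region is the convex hull of stable
anchors — matched neurons responsive at both timepoints whose preferred
orientation moved < 30° (strict) and preferred SF < 1 octave (strict);
the hull is the simplest circumscribing region consistent with a
"perimeter of unchanged neurons", and point membership is delegated to
`mgcv::in.out`. Within the region, unmatched or nonresponsive neurons
count as NR at that timepoint, and the 4x4 transition table's row sums
reproduce the per-category counts at the first timepoint exactly.
Exchanged-mask metrics report t2/t1 SNR and SR ratios for stable, lost,
and gained cohorts.

## Group statistics

Classical tests are delegated to base R (`ks.test`, `wilcox.test`,
`t.test`, `kruskal.test`, `aov`) behind a thin contract layer; only the
bespoke quantities (criteria, tuning formulas, matching, ODI) are
implemented here. The percent-responsive-per-SF summary uses a two-way
group x SF analysis of variance with each mouse as an independent
replicate (the repeated-measure alternative is not identifiable from a
single session per mouse) and Sidak-corrected per-SF contrasts,
`1 - (1 - p)^8`.

## Numerical choices and degenerate inputs

- Argmax ties anywhere break toward the smallest index (delay, then
  orientation, then SF), making all outputs deterministic.
- Zero-resultant orientation vectors, fully clipped SF curves, and
  all-zero response grids return `NA` markers; all-zero grids demote the
  neuron to nonresponsive with a warning.
- A zero noise SD makes SNR `Inf` with a warning rather than an error.
- Every stochastic routine takes an explicit seed and restores the
  caller's RNG state, so identical seeds give bit-identical schedules,
  populations, and traces.

## Problem sizes used by the tests

Parameter-recovery checks run 200 strongly tuned neurons (amplitude
median 2.5, noise SD 0.05) through one 600-s session per eye and ask for
median errors ≤ 10° (orientation, circular), ≤ 0.5 octave (SF), and
≤ 0.15 (ODI of binocular neurons); typical results are ~2°, ~0.1 octave,
and ~0.12. Classifier calibration uses 150 pure-baseline neurons.
Directional MD checks run 50 seeded simulations of 70-neuron mice for
the ODI and response-strength directions, and 50 seeded 657-neuron
populations at the generator level for the matching-dependent B→I rule.
These sizes are the package's own choice of a desk-scale experiment:
large enough for stable medians, small enough to iterate on.

## Known limitations

- The spike-rate estimator is deliberately simple; absolute rates are
  meaningless and only within-neuron comparisons are used.
- The synthetic forward model omits neuropil dynamics, motion, and
  correlated noise, so real-data thresholds (e.g. the exact spontaneous
  75th percentiles) will differ from synthetic ones.
- The stable-perimeter hull assumes convexity of the unchanged region.
- Ingest mode computes group summaries from any deposited-style
  per-neuron tuning table, but the published tables themselves are an
  external download and are not bundled; the bundled example table is
  synthetic.
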
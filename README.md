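# odplast

Analysis pipeline for **ocular dominance (OD) plasticity** measured with
two-photon calcium imaging in mouse binocular visual cortex. During the
critical period, closing the contralateral eye for a few days (monocular
deprivation, MD) shifts cortical responsiveness toward the open eye.
`odplast` quantifies that shift at single-neuron resolution: it turns
GCaMP6s fluorescence traces and a random-grating stimulus schedule into
per-neuron, per-eye responsiveness calls, orientation and
spatial-frequency (SF) tuning, ocular dominance indices, and — across
repeated imaging sessions — neuron-by-neuron category transitions.

A synthetic-data generator (stimulus schedules, ground-truth tuned
populations, Poisson spiking convolved with a GCaMP6s-like kernel, and an
MD perturbation model) makes the whole pipeline testable by parameter
recovery, with no raw recordings required.

## What it computes

- **Stimulus schedules** — 6 orientations (30° steps) x 8 SFs
  (0.028–0.48 cpd, half-octave steps) x 8 phases plus a blank, drawn
  randomly at 4 Hz under 15.5 Hz imaging (2,400 presentations per
  10-minute session).
- **Signals** — neuropil-corrected ROI traces (mean over mask minus
  annulus median), rolling-percentile dF/F, and a nonnegative inferred
  spike rate (ISR).
- **Responsiveness** — reverse correlation of the ISR to stimulus onsets
  over delays −2..18 frames; a neuron is responsive for an eye when its
  optimal delay is 4–9 frames, and both its SNR (evoked-window grid SD
  over flanking-window grid SD) and spike ratio SR (percent of preferred
  presentations answered) exceed the 75th percentiles of the session's
  spontaneously active neurons.
- **Tuning** — preferred orientation as half the argument of
  `sum_n O_n e^{i 2 pi theta_n / 180}`; preferred SF as
  `10^{sum_k Sf_k log10 omega_k / sum_k Sf_k}` after clipping tails at
  25% of peak; FWHM widths; per-SF significance vs blank
  (Kruskal–Wallis + Dunn's correction for 8 comparisons, P < 0.01).
- **Ocular dominance** — ODI = (C − I)/(C + I) on preferred-stimulus
  dF/F (monocular neurons pinned to ±1), per-mouse mean and
  strength-weighted summed ODI, binocular matching ΔOri (0–90°).
- **Longitudinal tracking** — mask matching at ≥50% overlap with no
  geometric transform, a stable-perimeter analysis region (anchors:
  Δori < 30°, ΔSF < 1 octave), 4x4 {C, B, I, NR} transition tables, and
  exchanged-mask SNR/SR ratios for lost vs gained neurons.

See `vignettes/odplast-methods.Rmd` for the models, defaults, and design
decisions.

## Worked example

```r
library(odplast)

sim <- simulate_mouse(n_neurons = 140, duration = 600, md = TRUE,
                      seed = 77002L)
a1 <- sim$analysis_t1   # P28 session
a2 <- sim$analysis_t2   # P32 after 4 days of MD

mouse_odi_summaries(a1$od)$mean_odi   # pre-MD contralateral bias
mouse_odi_summaries(a2$od)$mean_odi   # collapses after MD
```

Running the bundled drivers (`Rscript analysis/04_longitudinal.R`) on
this same mouse prints:

```
matched 140/140 ROIs (median overlap 1.00)
stable perimeter: 46 anchors, 117/140 neurons analyzed
category transitions (rows P28, columns P32MD):
    t2
t1    C  B I NR
  C  20 15 4  4
  B   1 11 7  4
  I   0  4 5  0
  NR  3  3 5 31
tracked-cohort mean ODI: 0.41 at P28 -> -0.09 at P32MD
```

i.e. the contralateral bias (mean ODI 0.41) collapses toward zero after
deprivation, driven by contralateral-monocular neurons gaining the open
eye (C→B), binocular neurons losing the deprived eye (B→I), and an
exchange of neurons into and out of visual circuitry (NR rows/columns).
The numbered scripts under `analysis/` walk the same dataset through
each stage (`01_simulate` → `05_group_stats`) and write their tables
under `results/`.

`ingest_tuning_table()` computes the same group summaries directly from
a deposited-style per-neuron tuning table (see
`inst/extdata/synthetic_tuning_table.tsv` for the expected layout).

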
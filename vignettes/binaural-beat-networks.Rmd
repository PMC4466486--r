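---
title: "Binaural-beat EEG analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binaural-beat EEG analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bbnet)
```

## The problem

A binaural beat (BB) is the illusory amplitude modulation heard when each
ear receives a pure tone and the two tones differ by a few hertz: the
percept beats at the frequency mismatch, although no physical sound does.
`bbnet` analyses multichannel EEG responses to such stimulation. It covers
the full chain — stimulus schedule, preprocessing, spectral power, phase
synchrony, functional networks and group statistics — and ships a
synthetic-EEG generator so that every stage has a ground-truth
parameter-recovery test.

The experimental design the package encodes is a blocked protocol: 34
blocks of 140 s, each consisting of 20 s silence, 60 s of a *non-binaural*
(NB) condition (200 Hz carrier in both ears) and 60 s of a *binaural*
(BB) condition (200 Hz left, 200 + f~bb~ Hz right). The beat frequency
f~bb~ steps through 1–20 Hz in 1 Hz steps and 20–48 Hz in 2 Hz steps; the
boundary value 20 Hz is emitted once, giving 34 distinct frequencies.
Beat frequencies are grouped by the classical EEG bands — delta (1–4 Hz),
theta (5–8), alpha (9–12), beta (13–30), gamma (32–48). Note one
documented discrepancy: the protocol's published description counts 8
beta and 14 gamma blocks, yet its own stepping rule yields 13 and 9; the
package follows the stepping rule and neither count is asserted against
the published text. Similarly, the published link-count formula
"64·(64−1)/2 = 2048" evaluates to 2016; the package always computes
n(n−1)/2 exactly.

## Analysis model

**Preprocessing.** A 4th-order Butterworth high-pass (0.5 Hz) applied
forward–backward removes drifts with zero net phase; the design order is a
choice (only the cutoff is part of the protocol), made to match the
zero-phase philosophy of the later band-pass stage. Recordings are
resampled to 256 Hz by polyphase FIR resampling. Each 60-s condition
segment loses 500 ms at each edge (onset/offset transients), leaving 59-s
epochs. Epoch boundaries are resolved from annotations, not sample
arithmetic, so resampling rounding cannot shift conditions.

**Spectral power.** Power spectral densities use Thomson multitapers with
time–bandwidth NW = 4 and 2·NW − 1 = 7 Slepian tapers on a 1024-point
FFT. A 59-s epoch at 256 Hz is split into consecutive non-overlapping
1024-sample (4 s) windows; tapered periodograms are averaged over tapers
and windows. This windowing is the one reading of "1024-point FFT on a
59-s epoch" consistent with the stated 4-s window and 0.25-Hz resolution;
overlapping windows would also be defensible but were not chosen. Band
power is the mean PSD over in-band bins, edges inclusive (the 0.25-Hz
grid places band edges exactly on bins). BB power is normalized by the
same block's NB power as 10·log₁₀(BB/NB) dB — a power-ratio convention,
since the normalized quantity is power. The steady-state response (SSR)
for a BB range is the normalized power of the *matching* EEG band (alpha
power under alpha-BB, etc.), averaged over electrodes and the range's
blocks.

**Phase synchrony.** Epochs are band-pass filtered with a windowed-sinc
(Hamming) linear-phase FIR applied forward–backward; the order is the
smallest even integer spanning three cycles of the band's lower edge.
Instantaneous phases come from the Hilbert analytic signal with the full
four-quadrant arctangent; one second per epoch edge is excluded from all
averages (filter + Hilbert transients). For channels *i, k* the cyclic
relative phase is the *signed* difference wrapped to [0, 2π). The
published definition wraps an absolute difference, but taken literally
that folds the sign and makes sign(sin φ) non-negative by construction,
which would destroy the phase lag index; the signed wrap is the reading
under which both indices behave as described. Two indices are computed:

* **PLV** = |⟨e^{iφ}⟩|: 1 for any constant lag, ~(π/4N)^{1/2} for N
  independent samples.
* **PLI** = |⟨sign sin φ⟩|, with sign(0) = 0: blind to zero-lag
  (volume-conduction-like) synchrony, 1 for a consistent non-zero lag.

The two are complementary: instantaneous mixing of independent sources
drives PLV up while PLI stays at its chance floor — the package's test
suite demonstrates exactly this. Whole epochs (minus edges) are used
rather than sub-windows; per-block adjacency matrices are averaged within
a BB range before statistics (averaging matrices rather than pooling
samples is the more robust choice and the aggregation level is otherwise
unspecified).

**Networks.** Adjacency matrices (symmetric, zero diagonal, weights in
[0, 1]) are reduced at fixed density: the round(k·n(n−1)/2) largest
off-diagonal weights are kept, ties broken by lexicographic pair order,
so all compared networks have identical link counts. Rounding to nearest
and the tie rule are package conventions (unstated in the protocol).
Three weighted measures follow: node strength (row sum), the
geometric-mean triangle clustering coefficient (C_i = 2t_i/(k_i(k_i−1)),
with t_i the halved sum of (a_ij·a_ih·a_jh)^{1/3} and C_i = 0 for degree
< 2), and local efficiency. The local-efficiency variant is the
inverse-distance mean on each node's neighbour subgraph with link lengths
1/weight and disconnected pairs contributing zero; the source analyses
cite the concept without a formula, so this standard weighted variant is
documented as the package's choice and is swappable in code. Global
values are arithmetic means of node values — exactly, by construction and
by test.

**Statistics.** The test battery mirrors the study design: a 2×2 mixed
ANOVA on SSR (Group × BeatFrequency alpha/gamma), one-sample t-tests per
SSR, a 2×5 mixed ANOVA of normalized alpha power over BB ranges, and
2 (Group) × 2 (Beat) × 5 (Range) mixed ANOVAs for each global network
measure at each density. Within effects are tested against their own
subject-interaction error strata; with 32 subjects the Beat × Range error
has (32 − 2)·4 = 120 degrees of freedom. No sphericity correction is
applied by default (the reference analyses report uncorrected df).
Electrode-level maps use paired (condition) or unpaired (group) t-tests
with Benjamini–Hochberg FDR at q = 0.05 (global level) or q = 0.1
(topographies). Two-tailed tests throughout. A rank-sum utility exists
for behavioural comparisons but is outside the main chain.

## The synthetic generator

No raw EEG accompanies the protocol, so the generator is a first-class
module: it emulates exactly the signal structure the pipeline measures,
with known ground truth.

Each channel is a sum of independent components, in microvolts:

* **1/f background** — white noise spectrally shaped to PSD ∝ 1/f
  (exponent 1.0 by default, flattened below 0.5 Hz), sd 10 µV.
* **Endogenous alpha** — Gaussian-shaped narrowband noise at 10 ± 1 Hz,
  sd 5 µV, giving the NB normalization baseline realistic alpha power.
* **Coupled oscillators** — a Kuramoto-style network of noisy phase
  oscillators at 10 Hz: phase *i* drifts at 2π·10 rad/s, diffuses with
  intensity matched to a 2-Hz linewidth, and is pulled toward
  θ_j − lag_ij with strength K_ij. The default topology is a ring with
  K = 15 rad/s and lag π/4, which produces genuinely *lagged* alpha
  synchrony (neighbour PLI ≈ 0.7 over 59 s) — visible to both PLV and
  PLI. Amplitude 5 µV (cosine of phase).
* **Zero-lag mixing** — an instantaneous mixing matrix (80 % self + 20 %
  common average by default) emulates volume conduction; it inflates PLV
  but not PLI.

BB epochs additionally carry the template effects the study reports, as
free magnitude parameters (no effect sizes are published, so magnitudes
are package choices stated here once): a 5 µV entrainment sinusoid at
f~bb~ in alpha-BB blocks (≈ +1.5 dB alpha SSR given the background
above), a ×1.5 endogenous-alpha power gain during delta-BB blocks
(cross-frequency response), and a −60 % change of the musicians' lagged
coupling during binaural theta/alpha-BB blocks (the group's connectivity
decrease). The entrainment component is modelled as *one* deep
steady-state source with a single phase, seen identically (zero lag) by
every electrode — the volume-conduction geometry the PLI rejects by
design. The alternative, an independently phased sinusoid per channel,
would inject constant non-zero inter-channel lags: the PLI would then
correctly report it as lagged synchrony, and the entrainment effect
would be inseparable from the coupling effects the template is meant to
isolate. The magnitudes were fixed from the signal-to-noise reasoning
above so that clearly-reported effects are recoverable at the reduced
test sizes; they are not fitted quantities.

Even so, injected effects interact: a strong common source dilutes the
phase estimates of genuinely coupled channels for *all* subjects in the
blocks where it is active. The recovery tests therefore inject effects
in isolation, one dataset for the power effects (delta/alpha/gamma
ranges) and one for the group coupling effect (theta/alpha ranges, the
ranges that contrast is defined on) — matching how each effect is
specified and keeping each check interpretable.

What the generator does *not* emulate: biophysical head volumes and
realistic lead fields, artifacts (blinks, EMG), non-stationary
background, between-subject spectral variability. Passing recovery tests
therefore show the pipeline recovers what the forward model injects —
they are evidence about the code, not about human EEG.

## Problem sizes and numerical choices

Test and example runs use reduced sizes chosen to exercise every code
path at desk scale: 2–6 channels and 4–16 s epochs for unit tests; the
end-to-end recovery runs use 16 channels, 4 subjects per group and full
59-s epochs on the schedule blocks of the ranges each injected effect is
defined on. Other conventions: kept-link
count rounds to nearest; degree counts non-zero links after thresholding;
sign(0) = 0 in the PLI; all-zero channels raise an error in phase
extraction rather than returning arbitrary phases; a constant response in
the mixed ANOVA yields F = 0, p = 1 by convention rather than 0/0; the
EDF writer pads to whole 1-s records. Seeds propagate deterministically:
a master seed derives per-subject seeds, and every random draw (including
the C++ oscillator integrator, whose noise is pre-drawn in R) flows from
them, so datasets are bit-reproducible.

## Known limitations

* The generator's oscillators live in the alpha band only; other bands
  contain only 1/f background, so cross-band *connectivity* effects are
  not simulated (cross-band power effects are).
* The EDF layer targets the package's own continuous recordings
  (EDF+C, one rate, 16-bit); it is not a general clinical-EDF reader.
* The published human F/t statistics are not reproducible without the
  undeposited recordings; the statistical surface is validated by
  calibration (type-I rates, FDR control) and by brute-force oracles
  instead.
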
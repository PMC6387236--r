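---
title: "Methods: posture classification and transition analysis for an instrumented chair"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: posture classification and transition analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sitpose)
```

## The measurement problem

An office chair instrumented with eight analog tactile pressure sensors
(ATS) — four under the seat fabric (ATS1–ATS4), four on the backrest
(ATS5–ATS8) — records how a seated person shifts posture while performing a
timed Stroop colour-word task. The sensors are textile resistive elements
with an *inverted* response: each channel outputs its maximum voltage when
unloaded and drops towards a minimum when pressed. They are treated strictly
as switches; no attempt is made to estimate continuous load, centre of
pressure, or postural dynamics.

A posture is an ordered 8-bit activation pattern: which sensors are pressed.
Eight combinations are recognised (P1–P8), from fully seated against the
backrest (P1, all eight active) through leaning forward off the backrest
(P6, seat only) to perching on the seat front against the upper backrest
(P8). Any other combination is `UNRECOGNIZED` and excludes the participant,
mirroring the study's attrition from 114 recordings to 92 after discarding
sensor failures and to 83 after discarding unrecognised combinations.

The Stroop task supplies a graded cognitive load. Its timing table expands
to 24 word slides over 85 s: six slides of colour names printed in black,
six congruent slides, then twelve incongruent slides of increasing word
count. Three half-open analysis windows follow: TI1 (black + congruent,
31 s), TI2 (incongruent with 3–6 words, 26 s), TI3 (incongruent with 9–12
words, 28 s). One posture is reported per window, and the analysis asks how
postures move between consecutive windows as engagement rises.

## Signal model and calibration

Every channel reads differently and every sitter loads the chair
differently, so thresholds cannot be fixed in advance. Each recording
therefore starts with two calibration segments:

* **no-load** (default 2 s): chair empty; the per-channel mean is `V_zero`;
* **seated-P1** (default 2 s): the participant sits fully against the
  backrest so every sensor is pressed; the per-channel mean is `V_maxload`.

The activation threshold per channel is the 50% point of the range,
`V_maxload + 0.5 (V_zero − V_maxload)` — invariant under affine rescaling of
the electronics. `V_maxload` is taken as the segment *mean*, not the
per-sample minimum: the loaded-state level is what matters, and a minimum
would be biased downward by noise. Calibration-segment lengths are not
fixed by the protocol; 2 s (90 samples at 45 Hz) keeps the standard error of
a baseline below about 11% of the noise standard deviation, and both lengths
are configurable.

Signals are sampled at 45 Hz and smoothed with a centred moving average
before thresholding. Only the cutoff (1 Hz) is part of the design; the
window length follows from the −3 dB criterion, `N = round(0.443 · fs /
f_c)`, giving N = 20 at 45 Hz. At 1 Hz the theoretical amplitude gain is the
Dirichlet-kernel value `|sin(πfN/fs) / (N sin(πf/fs))| ≈ 0.706`, which the
tests verify against the implementation to 1e−6. The window is centred
(zero phase, appropriate for offline analysis) and shrinks at the edges;
`NA` samples (dropouts) propagate through any window that contains them, so
faults cannot be smoothed away. A channel is *active* at a sample when its
filtered voltage is strictly below the threshold; a value exactly at the
threshold counts as inactive — a conservative tie rule on a measure-zero
event.

## From samples to one posture per interval

The study reports a single activation combination per interval but does not
state the aggregation rule. This package uses the **modal per-sample
pattern**: within each window the most frequent 8-tuple wins, with ties
broken by earliest occurrence inside the window. Aggregating patterns (not
posture labels) keeps the rule independent of the lookup, and the mode is
robust both to boundary smearing from the filter and to isolated noise
flips. Exclusion is listwise: a sensor failure (missing samples in the test
window, voltages outside the supply rails, or a channel with zero variance
over the entire recording) or any unrecognised interval removes the
participant from all downstream statistics.

Two defects in the published pattern table required decisions:

* **P7/P8 duplication.** As printed, P7 and P8 share the pattern `11000011`,
  although P7's description says the sitter is *not* leaning on the
  backrest. The default lookup corrects P7 to `11000000` (seat front only),
  which restores injectivity; the printed table remains constructible, but
  building a lookup from it fails loudly rather than classify ambiguously.
* **P4/P5 seat halves.** P4 ("right leg crossed") carries the seat pattern
  P3's description implies, and vice versa. The printed patterns are kept by
  default to reproduce the published classification; `swap_p4_p5 = TRUE`
  applies the description-consistent variant.

## The synthetic cohort

No recordings from the study are public, so the package generates its own.
The generator emulates exactly the features the analysis depends on:
per-channel distinct baselines (`V_zero` drawn from 2.8–3.3 V, `V_maxload`
from 0.8–1.3 V, mimicking sensors that each read differently), the inverted
two-level switch response, additive Gaussian noise and optional linear
drift, clipping at the supply rails, injectable channel faults (stuck at
either level, or dropout), and the two calibration segments preceding every
test. Posture changes are instantaneous at segment boundaries. Noise and
drift magnitudes are package parameters, not reported facts; the default
noise (20 mV) is small relative to a ~2 V dynamic range, as expected of a
resistive divider read by a 12-bit ADC, and robustness is probed explicitly
at a noise standard deviation of 5% of each channel's range.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: continuous and posture-dependent load levels,
partial contact, gradual postural drift within an interval, multiplexing
artefacts of the single-ADC acquisition, and within-cohort behavioural
variability beyond the scripted triples.

Cohort fixtures are built directly from the two published 8×8 transition
tables. Participants are enumerated over the TI1–TI2 table's cells in
row-major order; within each TI2 posture group, the TI2–TI3 table's
corresponding row is dealt out in ascending participant order. Pair-counting
the result returns both input tables cell-for-cell (the construction is the
identity on the tables), margins are validated first (the TI2 margin must
agree between the tables — it does, e.g. 44 participants in P1), and the
whole construction is deterministic. Because the two pairwise tables do not
determine the three-way joint distribution, triple-level quantities
(no-transition and non-monotonic counts) are properties of this coupling,
not of the study cohort: the package reports what it computes (16
no-transitions, 20 non-monotonic on the fixture) and does not pin the
study's descriptive counts (13 and 8).

## Transition statistics

Postures across two intervals form an 8×8 contingency table. For a posture
pair (Pi, Pj) with discordant counts `b` (i→j) and `c` (j→i), the pairwise
test is McNemar's chi-square with the Edwards continuity correction and **no
clamping** of the corrected difference:

> X² = (|b − c| − 1)² / (b + c), df = 1.

When `b = c` the numerator is (−1)² = 1, so a (1,1) pair yields X² = 0.5,
p ≈ 0.4795. This unclamped convention is the only one that reproduces all
nine pairwise p-values printed in the study from its own tables (base R's
`mcnemar.test`, by contrast, silently drops the correction on symmetric
tables; exact-binomial and uncorrected variants are available behind the
`variant` argument). A pair is tested only when **both** discordant counts
are positive — the eligibility rule inferred from which pairs the study
actually tested (pairs with a zero count were excluded even when b + c > 2).

P-values are displayed to three decimals (four below 0.001). Chi-square
tails of half-integer statistics land exactly on half-points of that grid
(0.4795), and such boundary values are tabulated rounding toward zero, the
convention of truncating displays — hence 0.479 for the (1,1) pairs.
Significance bands follow the study's reading: p < 0.05 significant,
0.05 ≤ p < 0.10 of interest.

Bowker's global symmetry test sums the *uncorrected* pairwise terms
(n_ij − n_ji)²/(n_ij + n_ji) over the pairs with any discordance, with df
equal to the number of included pairs (the standard convention). Under it,
the published tables give X² = 19.93 on 15 df (TI1–TI2) and X² = 30.88 on
16 df (TI2–TI3), i.e. p ≈ 0.17 and p ≈ 0.014 — *not* the global p-values
the study prints (0.083 and 0.0002), which imply mutually inconsistent
degrees of freedom and are not reproducible from the printed tables. The
implementation keeps the standard convention and documents the discrepancy
rather than tuning df; the Bowker statistic itself is verified against a
brute-force double loop.

A posture triple across TI1→TI2→TI3 is `NO_TRANSITION` when all three
postures agree, `NON_MONOTONIC` when a departed posture is revisited (with
three intervals, necessarily a return to the start), and `MONOTONIC`
otherwise.

## Numerical and design notes

* Time windows are half-open `[start, end)` seconds; samples are assigned by
  timestamp. Instruction screens (durations unstated in the protocol;
  default 0 s) shift window offsets, never durations.
* The timing table sums to 24 word slides although the protocol mentions 25;
  the extra slide is taken to be the instruction screen, and only the 24
  word slides are scheduled.
* Scale: the packaged analyses simulate the 83-participant cohort at 45 Hz
  over the 89 s recording (calibration + test), roughly 4,000 samples × 8
  channels per participant; a full noiseless end-to-end reproduction runs in
  a few seconds, and the ten-replicate noise study in well under a minute.
* Determinism: every stochastic step flows from one integer seed;
  per-participant seeds are derived from it, and reports serialize
  byte-identically on identical input.

## Known limitations

The two-level switch model cannot probe threshold placement against graded
loading, and the scripted cohort cannot probe the modal aggregation rule
against natural fidgeting. Triple-level descriptive counts depend on the
fixture's deterministic coupling (above). The Bowker global p-values of the
study are irreproducible from its printed tables; only the statistic's
construction is validated. Classification accuracy on real recordings —
beyond what calibration, filtering and thresholding guarantee under the
stated noise model — is outside what this package can establish.
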
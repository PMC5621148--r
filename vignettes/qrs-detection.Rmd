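---
title: "QRS detection and R-point recognition: method and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{QRS detection and R-point recognition: method and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qrsdetect)
```

## The problem

A single-lead wearable ECG monitor must find every heartbeat (the QRS
complex) and place the R point in real time, on hardware with very little
compute, in signals that carry baseline wander, amplitude changes from
electrode contact, and atypical beat shapes (bundle-branch blocks, premature
ventricular contractions, paced beats).  `qrsdetect` implements a
low-complexity detector built from three stages, plus the evaluation
machinery needed to score it beat by beat and a synthetic generator that
exercises every supported morphology with exact ground truth.

## The method

### Windowing

Monitored heart rates span 30–240 beats/min, so a 2-s window always holds at
least one full cardiac cycle.  The signal is processed in 2-s windows
refreshed every 1 s (`window_s`, `step_s`).  Each refreshed window is only
analyzed when its filtered peak-to-peak range strictly exceeds 0.5 mV
(`min_amp_mv`), the minimum credible QRS amplitude; flat or disconnected
segments are skipped outright.

### Signal enhancement

The window is band-pass filtered to 0.5–17 Hz and convolved with a zero-sum
enhancement mask of half-width $k$:

$$S(n) = \sum_{j=-k}^{k} M(k+j)\,E(n+j), \qquad
M = (\underbrace{-1,\dots,-1}_{k},\; 2k,\; \underbrace{-1,\dots,-1}_{k}).$$

For $k = 1$ this is the negated second difference: sharp deflections (QRS)
are amplified, smooth low-frequency waves (P, T, baseline wander) are
suppressed, and any affine trend $a + bn$ is annihilated exactly.  The
masked window is then normalized so its largest absolute value is 1, which
removes inter-subject amplitude differences and lets *static* thresholds
work downstream.  Normalization preserves sign, so inverted-QRS windows keep
their dominant troughs.  A window whose masked signal is numerically zero
(relative tolerance $10^{-9}$) carries no QRS-like activity and is rejected.

The default is $k = 1$ at every sampling rate; `k` is exposed in
`detector_config()` for experimentation.

### Fiducial point detection

On the normalized signal, every maximal run of samples above `pos_thr`
(0.22) is reduced to one crest (its maximum; earliest sample on ties) and
every run below `neg_thr` (−0.2) to one trough.  The run-level reduction
keeps sample noise from splitting one wave into several extrema.  Scanning
forward from the first supra-threshold sample, the extrema inside a 0.3-s
searching range decide one of four cases:

| case | condition | fiducial | resume |
|------|-----------|----------|--------|
| I    | exactly one crest, one trough | the crest | after the trough |
| II   | two crests, one trough between them | the trough | 0.12 s after it |
| III  | one crest $>$ 0.52, no trough | the crest | 0.12 s after it |
| IV   | anything else | none | at the next crest's onset |

Case I covers the common upright QRS (crest plus trailing trough of the
masked response).  Case II fires when the masked response is
crest–trough–crest — fork-like (rsR′) and deep-S/inverted complexes.  Case
III accepts a lone tall crest (seen in paced records).  Case IV re-anchors
the scan when large P waves or clutter produce too many extrema.

Three readings of the case conditions were genuinely open and are fixed
here as follows. *Case I* reads "only one crest and only one trough" as
exactly-one-of-each with no ordering constraint. *Case II* requires exactly
one trough in the whole range, not merely one between the crests. *Case
III* additionally requires zero troughs, otherwise it would shadow Case I.
The state machine is property-tested against an independent rule-table
oracle over randomized extremum layouts.

A starting point whose searching range would overrun the window's valid end
is deferred: the 1-s refresh guarantees the beat reappears fully covered in
the next window.  In the *last* window of a record no such window exists,
so the range is clipped at the valid end instead — without this the final
beat of every record would be structurally missed.  Each later window
reports only beats from its newer 1 s, extended backwards by one searching
range (0.3 s) to pick up the beats its predecessor deferred; residual
duplicates are collapsed by a 150-ms deduplication rule (the earlier
window's beat wins).  150 ms reuses the evaluation pairing radius: no two
physiological beats are that close even at 240 beats/min.

### R-point recognition

Q, Ra, R and S are located on a *separate* 0.5–40 Hz filtered copy of the
signal (`morph_high_hz`), not on the 17-Hz mask input: the wider band
preserves the QRS amplitude ratios that the quarter-amplitude rule below
depends on.  All searches happen in a 0.24-s span centered at the fiducial
point (twice a normal QRS duration), using the span's maximum and mean
amplitude as references:

1. **S**: from the fiducial forward, the first local maximum above half the
   span maximum (the R crest, if present) is the S start point, else the
   fiducial itself; S is the first local minimum after it below the span
   mean, with the post-start minimum sample as fallback.
2. **Ra**: if any local maximum before S exceeds half the span maximum, Ra
   is the highest sample before S (earliest on ties); otherwise Ra
   coincides with S.
3. **Q**: the mirror image of step 1, scanning backwards from Ra.
4. **R and template**: Ra = S gives R at S, template `d` (hidden R);
   $|m_{Ra}-m_Q| < \tfrac14 |m_{Ra}-m_S|$ gives R at S, template `c`
   (small R); otherwise R at Ra, template `b` for a Case-II (trough)
   fiducial and `a` otherwise.

"Local minimum slope" points are implemented as local minima of the signal
(first difference changes from negative to non-negative) since Q and S are
wave troughs in all four templates; this is the main interpretive decision
of the module.  The amplitude differences in the quarter rule are absolute
values.  Fallbacks guarantee totality: every valid fiducial yields a beat,
and the invariants $q \le ra \le s$, $r \in \{ra, s\}$ hold by
construction.  All comparisons are ratios or orderings, so beat recognition
is invariant to positive amplitude scaling.

### Evaluation

Detections and reference beats are paired one-to-one when their absolute
time difference is strictly below 150 ms, by a greedy forward sweep (each
reference takes the nearest unpaired detection; ties keep the earliest
detection — the tie-break for two equidistant detections is not prescribed
by the standard and is fixed here).  For references spaced more than twice
the tolerance apart the sweep provably equals the optimal bipartite
pairing, and it is tested against a brute-force dynamic-programming oracle
on random instances.  From the counts:

$$Se = \frac{TP}{TP+FN}\cdot 100\%, \quad
{+P} = \frac{TP}{TP+FP}\cdot 100\%, \quad
DER = \frac{FP+FN}{TP+FN}\cdot 100\%.$$

Zero denominators yield `NA`, never 0; `DER` may exceed 100 %.  Ventricular
flutter/fibrillation episodes (delimited by the database's flutter
start/end markers; an unclosed episode runs to the record end) are excluded
*symmetrically*: reference beats and detections inside an episode are both
dropped.  How in-episode detections should be counted is not stated in the
source material; symmetric exclusion is this package's choice.  The
per-rhythm table attributes TP/FN to the reference beat's annotation code;
false positives carry no rhythm label and appear only in totals, so the
table reports TB/TP/FN/Se only.

The denoising figure of merit is
$SNR_{imp} = 10\log_{10}\!\big(\sum|X_n-X|^2 / \sum|X_d-X|^2\big)$ dB,
validated through its closed forms (0 dB for the identity, $10\log_{10}2$
for halved residual energy).

## Tunable parameters

| parameter | default | unit | role |
|-----------|---------|------|------|
| `pos_thr` / `neg_thr` | 0.22 / −0.2 | — | crest/trough thresholds on the normalized transform |
| `high_thr` | 0.52 | — | lone-crest acceptance (Case III) |
| `search_range_s` | 0.3 | s | fiducial searching range |
| `qrs_dur_s` | 0.12 | s | nominal QRS duration; Case II/III skip-ahead |
| `min_amp_mv` | 0.5 | mV | window activation gate (strict) |
| `rspan_s` | 0.24 | s | Q/R/S searching span |
| `match_tol_s` | 0.15 | s | pairing and deduplication radius |
| `band_low_hz`–`band_high_hz` | 0.5–17 | Hz | mask input band |
| `morph_high_hz` | 40 | Hz | morphology band upper edge |
| `k` | 1 | samples | mask half-width |

## Filter realization

The filters are second-order Butterworth band-passes (`signal::butter`,
two poles per edge) applied *causally* with `signal::filter`, honoring the
method's sample-by-sample real-time claim; no zero-phase forward–backward
pass is used.  Whether the original benchmark used causal or zero-phase
filtering is unstated; causal is fixed here, and the consequence is a small
systematic group delay (a few samples at 360 Hz) between the masked
timeline and the morphology timeline, which the 0.24-s searching span
absorbs.  Given the coefficients from `signal::butter(2, c(0.5, 17)/180)`,
results are reproducible bit for bit.

## The synthetic generator

`generate_ecg()` builds beats as sums of Gaussian components — chosen over
dynamical-model synthesis for transparency and exact truth placement — at
cumulative RR times (0.25–2.0 s enforced), then adds optional sinusoidal
baseline wander and seeded white Gaussian noise; the truth is recorded
before noise.  Six morphologies are provided: the four recognition
templates `a` (normal), `b` (fork-like rsR′: a wide R bump carved by a
sharp notch), `c` (deep S, small R), `d` (QS with hidden R), plus
`inverted` and `bigP` stress variants.  The deep-S kinds carry a
discordant upright T wave shortly after the QRS, as paced and ventricular
beats do; besides being physiological, that T supplies the span maximum
that keeps the S-point search anchored when the QRS itself has no usable
crest.  The ground-truth R convention matches the detector's output
convention per template (R apex for `a`/`b`/`bigP`, S trough for
`c`/`d`/`inverted`), so 100 % sensitivity on clean signals is a fair
target.

What the generator does *not* emulate: electrode-pop artifacts, muscle
noise with realistic spectra, respiratory amplitude modulation, rhythm
transitions, or multi-lead morphology.  Passing the synthetic suite
therefore demonstrates the structural correctness of the pipeline — one
fiducial per beat across 60–180 beats/min, template recovery, wander
immunity — not clinical-grade performance; that claim belongs to the
full annotated-database benchmark (`benchmark_wfdb()`), which requires the
48 half-hour records to be present locally.

## Numerical choices and degenerate inputs

* Ties in argmax/argmin take the earliest index everywhere.
* A supra-threshold plateau contributes one crest at its first sample.
* The transform's `k` edge samples per side are invalid (set to 0 and
  excluded from normalization), not zero-padded — padding would fabricate
  edge crests.
* Case I resumes one sample after its trough; the state machine always
  advances at least one sample per iteration, and a fiducial equal to its
  predecessor is dropped, keeping output indices strictly increasing.
* The Q/R/S span is clipped at record edges; all searches tolerate empty
  candidate sets via the extreme-value fallbacks.
* An all-zero (or affine) window is rejected as "no QRS activity" rather
  than producing a 0/0 normalization.
* 1-based sample indices throughout (R convention); the time of sample
  $i$ is $(i-1)/f_s$ seconds.

## Problem sizes used in the shipped checks

The test-suite and acceptance-script simulations are sized to exercise
every code path while staying desk-sized: 120-beat clean sinus strips for
the sensitivity targets, 20 noise-free beats per template for recovery,
10-beat strips for wander comparisons, and 200 randomized instances for
each property oracle.  Longer strips change none of the reported numbers
on clean signals, since the pipeline is deterministic and
streaming-consistent.

## Known limitations

* **Broadband noise.** With static thresholds and a differencing mask, the
  detector is exact on clean synthetic signals up to about 0.02 mV rms of
  additive white noise (at 1 mV QRS) and degrades beyond (at 0.05 mV rms,
  sensitivity drops to ~60 % on the synthetic strips): threshold-crossing
  ripple splits crest runs and drives the state machine into Case IV.
  Real ambulatory interference is dominated by low frequencies, which the
  mask removes — the design trades white-noise immunity for simplicity.
* **No adaptive thresholds or refractory logic** beyond the stated 0.12-s
  skips; rhythms that modulate QRS amplitude within a window rely entirely
  on the per-window normalization.
* **Beat-type classification is not performed**: the template label is a
  morphology tag, not a diagnosis.
* The WFDB reader supports formats 212 and 16 (the formats used by the
  target database), single-record files, and MIT-format annotations.
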
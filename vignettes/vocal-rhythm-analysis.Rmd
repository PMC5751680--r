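---
title: "Measuring vocal rhythms in harbor seal pup calls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring vocal rhythms in harbor seal pup calls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sealrhythm)
```

## The measurement problem

A harbor seal pup in rehabilitation produces mother-attraction calls (MACs)
in *bouts*: runs of closely spaced calls separated by long silent gaps.
Three temporal variables capture the rhythm of such a sequence:

* **duration** of each call, `offset − onset`, in ms;
* **IOI** (inter-onset interval): time between the onsets of two
  consecutive retained calls;
* **IPI** (inter-peak interval): time between the maximum-intensity peaks
  of two consecutive retained calls.

Onsets and offsets come from a manual Praat TextGrid annotation; peaks come
from the audio itself via an intensity contour. Because the pooled interval
series mixes two timescales (within-bout intervals of ~2 s, between-bout
gaps of tens of seconds), a "short" subset is carved out with an adaptive
threshold — intervals within 4 times the series minimum — isolating timing
*within* bouts. Each series is summarised by n, mean, sample SD,
CV = SD/mean, min and max; the scientific comparisons are
distribution-level: a two-sample Kolmogorov–Smirnov test of IOI against
IPI, at both timescales. A low within-bout CV indicates temporal
regularity; agreement of IOI and IPI distributions means onset-based and
peak-based interval definitions are interchangeable for this animal.

## Pipeline stages and their assumptions

### Annotations (`read_textgrid`, `select_calls`)

Both Praat text dialects (long and short) are parsed, in UTF-8 or UTF-16
(detected from the byte-order mark Praat writes); the binary format is
rejected with a clear error. Times are seconds from file start, intervals
half-open `[onset, offset)`, the Praat convention. Call retention is
label-based: exact, case-sensitive match after whitespace stripping
(configurable), with `"MAC"` as the default retained category. The
annotation's literal category labels are configuration, not fact — any
label set can be retained. Intervals are computed between consecutive
*retained* calls even when an excluded call lies between them; no break
rule is applied, because retention is defined by the label filter alone.

### Intensity and peaks (`intensity_contour`, `call_peaks`)

The intensity at frame time *t* is
`10·log10( Σ w·x² / Σ w / (2·10⁻⁵)² )` — window-weighted mean-square
amplitude referenced to 20 µPa with full scale treated as amplitude 1.0, so
a unit sinusoid sits at 20·log10(0.70711/2·10⁻⁵) ≈ 90.97 dB. The default
window is Kaiser (β = 20) with *effective* duration `3.2/min_pitch`
(physical duration twice that) stepped by `0.8/min_pitch`; at the default
`min_pitch = 100` Hz this is the classic 32 ms / 8 ms analysis. A Hann
window of duration `3.2/min_pitch` is an accepted alternative. These are
reconstructions of standard Praat settings; no analysis setting is treated
as ground truth, which is why peak-based results are only ever compared at
the precision they are reported to.

Numerical choices: frames whose window is all-zero get a finite silence
floor (−300 dB) instead of −∞; ties at the maximum go to the earliest
frame (deterministic and order-independent); the peak is reported at frame
resolution, no parabolic interpolation. Peak times are therefore quantized
to the frame step — gain changes never move a peak, and delaying the signal
moves every peak by the delay within one step.

### Interval series (`call_durations`, `inter_onset_intervals`, `inter_peak_intervals`, `filter_short`)

Series values are positive milliseconds in temporal order, with
`|IOI| = |IPI| = n_calls − 1`. Values are stored at microsecond precision:
frame-time arithmetic otherwise leaves sub-nanosecond floating-point
residue that would break exact-equality comparisons (a KS test of two
identical-by-construction series must give D = 0). CSV output is rounded
to 0.1 ms, the precision of the reported statistics.

The short-interval threshold defaults to `4 × min` of the series being
filtered, computed independently for IOI and IPI; a fixed absolute
threshold (e.g. 3900 ms) is available as an override, because the published
"≈ 3900 ms" is ambiguous between the adaptive rule and its rounded result.
The boundary is inclusive (`value ≤ threshold`), reading "within 4 times
the minimum" inclusively; the flag `boundary_inclusive = FALSE` flips it.

### Statistics (`summarize_series`, `ks_two_sample`)

SD uses the sample (n − 1) denominator, the bioacoustics convention. A
single-value series flags SD and CV as `NA` rather than silently reporting
0. The KS statistic is computed from first principles by a single merge
pass over the pooled sorted sample (+1/n₁ steps for one sample, −1/n₂ for
the other; with ties, only the cumulative value after a tied group is a
valid ECDF difference). The p-value is the asymptotic Kolmogorov survival
function `Q(λ) = 2·Σ (−1)^{k−1} e^{−2k²λ²}` at `λ = D·√(n₁n₂/(n₁+n₂))`,
clamped to [0, 1], with no continuity correction and no exact small-sample
computation — the standard reconstruction when only "D, p" is reported.
The unit tests cross-check D against a brute-force pooled-point oracle and
against `stats::ks.test(exact = FALSE)`, and verify type-I calibration at
n = 50 empirically.

## The synthetic generator

`synthetic_spec()` defines the study conditions the analysis assumes:

| parameter | default | why |
|---|---|---|
| `duration` | Normal(976.1, 205.7) ms, floor 100 ms | published duration mean/SD |
| `within_ioi` | moment-matched truncated Normal: realized mean 1983.2, SD 722.1, floor 1000 ms | published within-bout IOI statistics |
| `calls_per_bout` | 1 + Poisson(1) | see mixture calibration below |
| `between_gap` | LogNormal(mean 15173.4, SD 5865.2) ms, floor 5000 ms | see mixture calibration below |
| `peak_rel_pos` | fixed 0.3 | energy peak in the first third of the call |
| `rate` | 48 kHz (24-bit WAV) | the original recording format; tests render at 8 kHz |

**Mixture calibration.** With bouts of `1 + Poisson(1)` calls, on average
half of all onset-to-onset intervals are within-bout and half are
between-bout gaps. Given the within component (1983.2, 722.1), the
between-gap moments were solved so that the pooled mixture reproduces the
published pooled IOI mean 8578.3 ms and SD 7807.4 ms exactly in
expectation:

* mean: 0.5·1983.2 + 0.5·m = 8578.3 ⟹ m = 15173.4;
* variance: 0.5·(722.1² + Δ₁²) + 0.5·(σ² + Δ₂²) = 7807.4² with
  Δᵢ the component-mean offsets ⟹ σ = 5865.2.

This yields the published two-timescale contrast (pooled CV ≈ 0.91,
within-bout CV ≈ 0.36) as an emergent property rather than a tuned one.

**Why moment-matched truncation.** Calls must not overlap their
successors, so within-bout intervals need a floor near one call duration.
Truncating a Normal(1983.2, 722.1) at such a floor would inflate its
realized mean by roughly 120 ms, silently violating the statistics the
generator is supposed to emulate. `dist_truncnorm()` instead solves for
underlying parameters (µ ≈ 1197, σ ≈ 1138) whose *post-truncation* mean
and SD are the published values. The 1000 ms floor also reproduces the
real recording's empirical minimum interval (~975 ms), which matters
because the short-interval threshold is defined off that minimum: under the
defaults it lands at 4000–4400 ms, cleanly between the within-bout
distribution and the 5 s between-gap floor.

**Non-overlap without bias.** The generator draws each onset gap first and
then draws the call's duration truncated below that gap, rather than
truncating the interval above the duration. This keeps the interval
distributions — the quantities under study — unbiased, at the cost of a
few-ms downward bias in durations (well inside the Monte-Carlo bounds the
tests use). A gap too small for any plausible duration is itself redrawn a
bounded number of times, so only genuinely infeasible specifications (e.g.
fixed 1000 ms durations under fixed 500 ms intervals) error out.

**Rendering.** Each call is a harmonic stack (fundamental 350 Hz, four
harmonics; white noise optional) shaped by a piecewise-linear envelope
whose vertex sits at the true peak time; a −70 dB Gaussian noise floor
fills the silences and the result is normalized to 0.9 full scale. With a
constant envelope shape — constant relative peak position *and* constant
duration — every call has the same onset-to-peak offset, so extracted IPIs
equal extracted IOIs up to one frame step. With varying durations a
constant *relative* peak position moves the *absolute* peak offset
proportionally, and IPI legitimately differs from IOI; the tests
distinguish these two regimes deliberately.

**What the generator does not emulate:** realistic seal-call spectra
(formant structure, fundamental contours), amplitude variation across
calls, annotation errors (onset/offset jitter, missed or spurious calls),
overlapping vocalizations, or non-stationarity across the recording.
Passing parameter-recovery tests therefore shows the measurement chain is
correct and unbiased under clean conditions; it does not certify
robustness to annotation noise.

## Test problem sizes

The test-suite scales were chosen to keep Monte-Carlo bounds meaningful at
interactive runtimes: KS oracle agreement on 1000 random tied instances;
null calibration with 2000 replicates at n = 50 (asymptotic p, rejection
rate checked against a widened binomial band [0.02, 0.09] to absorb
asymptotic error); parameter recovery through the full audio pipeline on
ten 50-bout recordings (about 14 minutes of audio each) rendered at 8 kHz,
with recovered grand means required to fall within 3σ/√n of the generating
values; and the IPI-tracks-IOI check on five constant-duration 50-bout
recordings.

## Known limitations

* The intensity analysis settings are reconstructions of standard Praat
  defaults; peak *times* are robust to them, but peak-based intervals
  inherit frame-step quantization (8 ms by default).
* The asymptotic KS p-value is conservative at small n; an exact
  computation is deliberately out of scope.
* The CV reported for the within-bout IPI series in the original write-up
  (0.39) is not exactly reproducible from its published mean and SD
  (803.3/2020.8 rounds to 0.40), suggesting truncation rather than
  rounding there; that single cell is excluded from reconstruction checks.
* Whether an intervening excluded call should break the interval chain is
  undefined in the source workflow; this package does not break the chain,
  and exposes the retained-label set so users can test the alternative.
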
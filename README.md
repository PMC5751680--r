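# sealrhythm

Timing analysis of harbor seal (*Phoca vitulina*) pup vocalizations.

Vocal rhythm — *when* an animal calls, not just how its calls sound — is a
key but under-measured dimension of animal communication. `sealrhythm`
implements, as a tested and reusable R pipeline, the workflow used to
quantify the spontaneous vocal rhythms of a harbor seal pup from an
annotated field recording:

1. parse a **Praat TextGrid** annotation and retain only the calls of
   interest (by default the mother-attraction calls, "MAC");
2. read the **PCM WAV** recording and compute a Praat-style **intensity
   contour** (windowed mean-square energy in dB), locating each call's
   maximum-intensity peak;
3. derive the three temporal variables and their within-bout subsets —
   call **durations**, **inter-onset intervals** (IOI, onset-to-onset of
   consecutive calls) and **inter-peak intervals** (IPI, peak-to-peak),
   plus the "short" series IOI^s^/IPI^s^ of intervals within 4× the series
   minimum (≈ 3900 ms on the original recording), which isolate timing
   *within* vocalization bouts;
4. summarise each series (n, mean, SD, **coefficient of variation**
   CV = SD/mean, min, max) and compare IOI with IPI at both timescales
   using a **two-sample Kolmogorov–Smirnov test** (D from the supremum
   ECDF distance; asymptotic p from
   Q(λ) = 2·Σ_{k≥1} (−1)^{k−1} e^{−2k²λ²}, λ = D·√(n₁n₂/(n₁+n₂))).

The original ~10-minute recording is not deposited, so the package ships a
first-class **synthetic generator**: bout-structured call sequences whose
duration and interval distributions default to the published statistics of
the recording, rendered to WAV + TextGrid + ground-truth JSON. Every
pipeline stage is validated against it — from closed-form intensity checks
to end-to-end parameter recovery.

The package is tidyverse-native: functions take data frames and return
tibbles, fitted results have `tidy()`/`glance()` methods, and result types
have `autoplot()` methods.

## Worked example

Generate a synthetic recording of 8 bouts (defaults mirror the published
timing statistics), run the full extraction, and inspect the report:

```r
library(sealrhythm)

spec   <- synthetic_spec(n_bouts = 8, rate = 8000, seed = 42)
fx     <- emit_fixture(spec, "demo")               # WAV + TextGrid + truth.json
report <- run_extraction(fx$wav, fx$textgrid, "demo-out")
report
#> Vocal rhythm report (sealrhythm 0.1.0)
#>
#>       kind  n    mean       sd       cv      min      max
#>   duration 19  916.09  209.131 0.228286  479.497  1300.23
#>        IOI 18 7091.82 7009.113 0.988338 1045.481 20825.63
#>        IPI 18 7096.00 6971.383 0.982438 1088.000 20768.00
#>  IOI_short 11 2136.76 1026.375 0.480343 1045.481  3798.58
#>  IPI_short 11 2173.09 1040.069 0.478613 1088.000  3936.00
#>
#> IOI vs IPI: D = 0.11, p = 1.00 (n1 = 18, n2 = 18)
#> IOI short vs IPI short: D = 0.18, p = 0.99 (n1 = 11, n2 = 11)
```

Reading the output: the pooled IOI series has CV ≈ 0.99 — the SD is about
as large as the mean, because it mixes short within-bout intervals with
long between-bout gaps — while the within-bout subset (`IOI_short`) is far
more regular. Onset-based and peak-based intervals tell the same story at
both timescales (the KS comparisons find no distributional difference),
which is the substantive result the pipeline is built to measure. With only
8 bouts the summary values fluctuate noticeably around the generating
parameters; at study scale (50 bouts) they converge toward the published
means (976.1 ms durations, within-bout IOIs around 1983.2 ms).

`run_extraction()` also writes the five CSVs named after the deposited data
files (`durations_all.csv`, `IOI_all.csv`, `IPI_all.csv`, `IOI_short.csv`,
`IPI_short.csv`) plus `report.json`. `run_stats()` recomputes the report
from such CSVs alone — including the deposited figshare files, if you have
them — without audio. A thin command-line wrapper with
`extract | stats | simulate | compare` subcommands lives in
`inst/cli/sealrhythm.R`.

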
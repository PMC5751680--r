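Package: sealrhythm
Title: Timing Analysis of Harbor Seal Pup Vocalizations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying spontaneous vocal rhythms in annotated
    audio recordings of harbor seal (Phoca vitulina) pup calls. Reads and
    writes Praat TextGrid annotations, computes Praat-style intensity
    contours from PCM WAV audio, extracts call durations, inter-onset
    intervals (IOI) and inter-peak intervals (IPI), isolates within-bout
    ("short") intervals by an adaptive threshold, and summarises the
    resulting interval series with descriptive statistics (mean, SD,
    coefficient of variation) and two-sample Kolmogorov-Smirnov
    comparisons. A synthetic bout-structured call generator produces
    WAV + TextGrid + ground-truth fixtures with controllable duration,
    interval and envelope-peak distributions, so the whole pipeline can be
    exercised and validated without the original field recording.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
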
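# Shared fixtures: hand-written TextGrid dialects, tiny call tables, and
# degenerate synthetic specs used across the test files.

# Long-dialect TextGrid with one tier of three intervals: "", "MAC", "".
long_textgrid_lines <- function() c(
  'File type = "ooTextFile"',
  'Object class = "TextGrid"',
  "",
  "xmin = 0",
  "xmax = 10",
  "tiers? <exists>",
  "size = 1",
  "item []:",
  "    item [1]:",
  '        class = "IntervalTier"',
  '        name = "calls"',
  "        xmin = 0",
  "        xmax = 10",
  "        intervals: size = 3",
  "        intervals [1]:",
  "            xmin = 0",
  "            xmax = 1.5",
  '            text = ""',
  "        intervals [2]:",
  "            xmin = 1.5",
  "            xmax = 2.75",
  '            text = "MAC"',
  "        intervals [3]:",
  "            xmin = 2.75",
  "            xmax = 10",
  '            text = ""'
)

# The same annotation in the short dialect.
short_textgrid_lines <- function() c(
  'File type = "ooTextFile"',
  'Object class = "TextGrid"',
  "",
  "0",
  "10",
  "<exists>",
  "1",
  '"IntervalTier"',
  '"calls"',
  "0",
  "10",
  "3",
  "0",
  "1.5",
  '""',
  "1.5",
  "2.75",
  '"MAC"',
  "2.75",
  "10",
  '""'
)

# Call table with onsets/offsets in seconds; peaks at a constant relative
# position when requested.
make_calls <- function(onsets, durations, peak_rel = NULL) {
  d <- tibble::tibble(onset = onsets, offset = onsets + durations)
  if (!is.null(peak_rel)) d$peak_time <- d$onset + peak_rel * durations
  d
}

# Random valid tier tiling [0, xmax] on a millisecond grid.
random_tiling_tier <- function(n_intervals, xmax = 30, tier = "calls") {
  cuts <- sort(sample(seq(1, xmax * 1000 - 1), n_intervals - 1)) / 1000
  bounds <- c(0, cuts, xmax)
  tibble::tibble(
    tier = tier, tier_xmin = 0, tier_xmax = xmax,
    label = sample(c("", "MAC", "other"), n_intervals, replace = TRUE),
    onset = bounds[-length(bounds)], offset = bounds[-1]
  )
}

# Degenerate spec: every distribution a point mass, cheap 8 kHz rendering.
degenerate_spec <- function(n_bouts = 1, calls_per_bout = 3,
                            ioi = 2000, dur = 1000, peak = 0.3, seed = 1) {
  synthetic_spec(
    n_bouts = n_bouts,
    calls_per_bout = dist_fixed(calls_per_bout),
    within_ioi = dist_fixed(ioi),
    duration = dist_fixed(dur),
    peak_rel_pos = dist_fixed(peak),
    rate = 8000, noise_floor_db = NULL, seed = seed
  )
}

# Brute-force KS D: max ECDF distance over pooled unique points.
ks_d_bruteforce <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(ecdf_value(a, pts) - ecdf_value(b, pts)))
}
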
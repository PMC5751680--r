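test_that("degenerate distributions give exactly spaced calls and peaks", {
  truth <- sample_sequence(degenerate_spec())
  expect_equal(nrow(truth), 3)
  expect_equal(diff(truth$onset), c(2, 2))
  expect_equal(truth$offset - truth$onset, rep(1, 3))
  expect_equal(truth$peak_time, truth$onset + 0.3)
  expect_equal(truth$bout, rep(1L, 3))
})

test_that("sampling is reproducible from the seed", {
  spec <- synthetic_spec(n_bouts = 5, rate = 8000, seed = 99)
  t1 <- sample_sequence(spec)
  t2 <- sample_sequence(spec)
  expect_equal(t1, t2)
  t3 <- sample_sequence(spec, seed = 100)
  expect_false(isTRUE(all.equal(t1$onset, t3$onset)))
})

test_that("calls never overlap and truth peaks lie inside their calls", {
  for (seed in 1:5) {
    spec <- synthetic_spec(n_bouts = 6, rate = 8000, seed = seed)
    truth <- sample_sequence(spec)
    expect_true(all(diff(truth$onset) > 0))
    expect_true(all(truth$onset[-1] > truth$offset[-nrow(truth)]))
    expect_true(all(truth$peak_time > truth$onset & truth$peak_time < truth$offset))
  }
})

test_that("within-bout interval means match the spec within CLT bounds", {
  spec <- synthetic_spec(n_bouts = 50, calls_per_bout = dist_fixed(5),
                         rate = 8000, seed = 7)
  truth <- sample_sequence(spec)
  gaps <- diff(truth$onset) * 1000
  within <- gaps[truth$bout[-1] == truth$bout[-nrow(truth)]]
  expect_equal(length(within), 50 * 4)
  expect_lt(abs(mean(within) - 1983.2), 3 * 722.1 / sqrt(length(within)))
  durs <- (truth$offset - truth$onset) * 1000
  expect_lt(abs(mean(durs) - 976.1), 3 * 205.7 / sqrt(length(durs)))
})

test_that("pooled intervals show the two-timescale CV contrast", {
  spec <- synthetic_spec(n_bouts = 60, rate = 8000, seed = 21)
  truth <- sample_sequence(spec)
  gaps <- diff(truth$onset) * 1000
  is_within <- truth$bout[-1] == truth$bout[-nrow(truth)]
  cv <- function(v) sd(v) / mean(v)
  expect_gt(cv(gaps), cv(gaps[is_within]))
  expect_gt(cv(gaps), 0.6)       # pooled series is strongly bimodal in scale
  expect_lt(cv(gaps[is_within]), 0.5)  # within-bout timing is regular
})

test_that("an infeasible spec errors after bounded resampling", {
  spec <- synthetic_spec(n_bouts = 1, calls_per_bout = dist_fixed(3),
                         within_ioi = dist_fixed(500),
                         duration = dist_fixed(1000), rate = 8000)
  expect_error(sample_sequence(spec, seed = 1), "infeasible")
})

test_that("rendering an empty sequence yields silence of the default length", {
  spec <- synthetic_spec(n_bouts = 0, rate = 8000, noise_floor_db = NULL)
  truth <- sample_sequence(spec, seed = 1)
  w <- render_audio(truth, spec)
  expect_equal(length(w$samples), 2 * 8000)
  expect_true(all(w$samples == 0))
})

test_that("rendered single call peaks where the truth says", {
  spec <- degenerate_spec(calls_per_bout = 1)
  truth <- sample_sequence(spec)
  w <- render_audio(truth, spec)
  ic <- intensity_contour(w)
  pk <- peak_in_interval(ic, truth$onset, truth$offset)
  expect_lt(abs(pk$peak_time - truth$peak_time), attr(ic, "time_step") + 1e-9)
})

test_that("doubling the envelope amplitude leaves the detected peak unchanged", {
  spec <- degenerate_spec(calls_per_bout = 1)
  truth <- sample_sequence(spec)
  w <- render_audio(truth, spec)
  w2 <- waveform(pmin(pmax(2 * w$samples, -1), 1) / 2, w$rate)  # same shape, rescaled
  p1 <- peak_in_interval(intensity_contour(w), truth$onset, truth$offset)
  p2 <- peak_in_interval(intensity_contour(w2), truth$onset, truth$offset)
  expect_equal(p1$peak_time, p2$peak_time)
})

test_that("overlapping calls refuse to render", {
  spec <- degenerate_spec()
  truth <- tibble::tibble(bout = 1L, call = 1:2, label = "MAC",
                          onset = c(0.5, 1.0), offset = c(1.2, 1.8),
                          peak_time = c(0.8, 1.3))
  expect_error(render_audio(truth, spec), "overlapping")
})

test_that("emit_fixture writes a parseable, consistent fixture", {
  out <- withr::local_tempdir()
  spec <- degenerate_spec(n_bouts = 2, calls_per_bout = 2, seed = 5)
  fx <- emit_fixture(spec, out)
  expect_true(all(file.exists(fx$wav, fx$textgrid, fx$truth_json)))

  tg <- read_textgrid(fx$textgrid)
  macs <- select_calls(tg, "MAC")
  expect_equal(nrow(macs), nrow(fx$truth))
  expect_equal(macs$onset, fx$truth$onset, tolerance = 1e-9)

  truth_json <- jsonlite::read_json(fx$truth_json, simplifyVector = TRUE)
  expect_equal(truth_json$seed, 5)
  expect_equal(truth_json$calls$onset, fx$truth$onset, tolerance = 1e-8)

  w <- read_wav(fx$wav)
  expect_equal(w$rate, 8000)
  expect_equal(max(abs(w$samples)), 0.9, tolerance = 1e-5)
})

test_that("distractor 'other' calls are emitted but excluded by selection", {
  out <- withr::local_tempdir()
  spec <- synthetic_spec(n_bouts = 3, calls_per_bout = dist_fixed(2),
                         other_calls = 2, rate = 8000, seed = 8)
  fx <- emit_fixture(spec, out)
  tg <- read_textgrid(fx$textgrid)
  expect_equal(sum(trimws(tg$label) == "other"), 2)
  macs <- select_calls(tg, "MAC")
  expect_equal(nrow(macs), 6)
})

test_that("truth.json is byte-identical across runs with the same seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  spec <- synthetic_spec(n_bouts = 2, rate = 8000, seed = 42)
  emit_fixture(spec, d1)
  emit_fixture(spec, d2)
  expect_identical(readLines(file.path(d1, "truth.json")),
                   readLines(file.path(d2, "truth.json")))
})
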
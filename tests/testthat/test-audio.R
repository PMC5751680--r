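# Raw RIFF writer used to craft inputs write_wav() cannot produce
# (stereo, float32, hand-picked sample words).
write_raw_wav <- function(path, data_bytes, channels, rate, bits, fmt_code = 1L) {
  bytes_per <- bits / 8
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + length(data_bytes)), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(as.integer(fmt_code), con, size = 2, endian = "little")
  writeBin(as.integer(channels), con, size = 2, endian = "little")
  writeBin(as.integer(rate), con, size = 4, endian = "little")
  writeBin(as.integer(rate * bytes_per * channels), con, size = 4, endian = "little")
  writeBin(as.integer(bytes_per * channels), con, size = 2, endian = "little")
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(length(data_bytes)), con, size = 4, endian = "little")
  writeBin(data_bytes, con)
}

test_that("a second of digital zeros reads back as 48000 zero samples", {
  tmp <- withr::local_tempfile(fileext = ".wav")
  write_wav(waveform(numeric(48000), 48000), tmp, bit_depth = 24)
  w <- read_wav(tmp)
  expect_equal(length(w$samples), 48000)
  expect_equal(w$rate, 48000)
  expect_true(all(w$samples == 0))
})

test_that("a full-scale positive 24-bit sample reads as 1.0 within one LSB", {
  tmp <- withr::local_tempfile(fileext = ".wav")
  write_raw_wav(tmp, as.raw(c(0xFF, 0xFF, 0x7F)), channels = 1,
                rate = 48000, bits = 24)
  w <- read_wav(tmp)
  expect_equal(length(w$samples), 1)
  expect_lt(abs(w$samples - 1), 2^-23 + 1e-12)
})

test_that("16-bit and 24-bit round-trips preserve samples to quantization", {
  x <- sin(2 * pi * 440 * (0:4799) / 48000) * 0.8
  for (bits in c(16, 24)) {
    tmp <- withr::local_tempfile(fileext = ".wav")
    write_wav(waveform(x, 48000), tmp, bit_depth = bits)
    w <- read_wav(tmp)
    expect_equal(w$samples, x, tolerance = 2^-(bits - 9))
  }
})

test_that("float32 WAV data is read unscaled", {
  x <- c(-0.5, 0, 0.25, 1)
  tmp <- withr::local_tempfile(fileext = ".wav")
  write_raw_wav(tmp, writeBin(x, raw(), size = 4, endian = "little"),
                channels = 1, rate = 8000, bits = 32, fmt_code = 3L)
  w <- read_wav(tmp)
  expect_equal(w$samples, x, tolerance = 1e-7)
})

test_that("identical stereo channels downmix to either channel, with warning", {
  x <- as.integer(round(sin(2 * pi * 100 * (0:799) / 8000) * 2^14))
  inter <- as.vector(rbind(x, x))  # L R L R ...
  tmp <- withr::local_tempfile(fileext = ".wav")
  write_raw_wav(tmp, writeBin(inter, raw(), size = 2, endian = "little"),
                channels = 2, rate = 8000, bits = 16)
  expect_warning(w <- read_wav(tmp), "downmixing")
  expect_equal(w$samples, x / 2^15)
})

test_that("non-WAV and compressed inputs raise format errors", {
  tmp <- withr::local_tempfile(fileext = ".wav")
  writeBin(as.raw(1:64), tmp)
  expect_error(read_wav(tmp), "RIFF")
  tmp2 <- withr::local_tempfile(fileext = ".wav")
  write_raw_wav(tmp2, as.raw(rep(0, 8)), channels = 1, rate = 8000,
                bits = 16, fmt_code = 85L)  # MP3 format tag
  expect_error(read_wav(tmp2), "unsupported WAV codec")
})

test_that("a unit-amplitude sinusoid sits at the closed-form 90.97 dB", {
  w <- waveform(sin(2 * pi * 1000 * (0:47999) / 48000), 48000)
  ic <- intensity_contour(w)
  expected <- 20 * log10((1 / sqrt(2)) / 2e-5)
  expect_equal(expected, 90.969, tolerance = 1e-4)
  expect_true(all(abs(ic$intensity - expected) < 0.1))
})

test_that("halving the amplitude lowers the contour by 6.02 dB everywhere", {
  w <- waveform(sin(2 * pi * 1000 * (0:47999) / 48000), 48000)
  half <- waveform(w$samples / 2, w$rate)
  drop <- intensity_contour(w)$intensity - intensity_contour(half)$intensity
  expect_true(all(abs(drop - 20 * log10(2)) < 0.01))
})

test_that("an all-zero signal sits at the silence floor", {
  ic <- intensity_contour(waveform(numeric(48000), 48000))
  expect_true(all(ic$intensity == -300))
  ic2 <- intensity_contour(waveform(numeric(48000), 48000), silence_floor = -200)
  expect_true(all(ic2$intensity == -200))
})

test_that("a too-short recording errors", {
  expect_error(intensity_contour(waveform(numeric(100), 48000)),
               "shorter than one analysis window")
})

test_that("a triangular-envelope call peaks at its vertex", {
  rate <- 8000
  t <- (0:(2 * rate - 1)) / rate
  onset <- 0.5; offset <- 1.5; vertex <- onset + 0.3 * (offset - onset)
  env <- pmax(0, pmin((t - onset) / (vertex - onset),
                      (offset - t) / (offset - vertex)))
  w <- waveform(env * sin(2 * pi * 1000 * t), rate)
  ic <- intensity_contour(w)
  pk <- peak_in_interval(ic, onset, offset)
  expect_lt(abs(pk$peak_time - vertex), attr(ic, "time_step") + 1e-9)
})

test_that("ties go to the earliest frame and single-frame intervals work", {
  rate <- 8000
  w <- waveform(rep(0.5, 2 * rate), rate)  # constant amplitude
  ic <- intensity_contour(w)
  pk <- peak_in_interval(ic, 0.5, 1.5)
  first_frame <- min(ic$time[ic$time >= 0.5])
  expect_equal(pk$peak_time, first_frame)

  one <- ic$time[10]
  pk1 <- peak_in_interval(ic, one - 1e-6, one + 1e-6)
  expect_equal(pk1$peak_time, one)

  expect_error(peak_in_interval(ic, one + 1e-6, one + 2e-6), "smaller time_step")
})

test_that("peak times are shift-equivariant and gain-invariant", {
  rate <- 8000
  t <- (0:(2 * rate - 1)) / rate
  onset <- 0.4; offset <- 1.2; vertex <- onset + 0.6 * (offset - onset)
  env <- pmax(0, pmin((t - onset) / (vertex - onset),
                      (offset - t) / (offset - vertex)))
  x <- env * sin(2 * pi * 800 * t)
  ic <- intensity_contour(waveform(x, rate))
  pk <- peak_in_interval(ic, onset, offset)

  delta <- 0.25
  shifted <- waveform(c(numeric(delta * rate), x), rate)
  pk_s <- peak_in_interval(intensity_contour(shifted), onset + delta, offset + delta)
  step <- attr(ic, "time_step")
  expect_lt(abs(pk_s$peak_time - (pk$peak_time + delta)), step + 1e-9)

  ic_g <- intensity_contour(waveform(3 * x, rate))
  pk_g <- peak_in_interval(ic_g, onset, offset)
  expect_equal(pk_g$peak_time, pk$peak_time)
})

test_that("the hann window configuration reproduces the same closed forms", {
  w <- waveform(sin(2 * pi * 1000 * (0:47999) / 48000), 48000)
  ic <- intensity_contour(w, window = "hann")
  expected <- 20 * log10((1 / sqrt(2)) / 2e-5)
  expect_true(all(abs(ic$intensity - expected) < 0.1))
})

test_that("call_peaks augments calls in onset order", {
  rate <- 8000
  spec <- degenerate_spec()
  truth <- sample_sequence(spec)
  w <- render_audio(truth, spec)
  ic <- intensity_contour(w)
  calls <- make_calls(truth$onset, truth$offset - truth$onset)
  out <- call_peaks(calls[c(2, 1, 3), ], ic)
  expect_equal(out$onset, truth$onset)
  expect_true(all(out$peak_time >= out$onset & out$peak_time < out$offset))
})
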
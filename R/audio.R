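#' Read a PCM WAV file
#'
#' Reads RIFF/WAVE audio: integer PCM at 16 or 24 bit, or IEEE float32.
#' Samples are scaled to `[-1, 1]` by the integer full-scale value
#' (`2^15` / `2^23`). Multi-channel input is downmixed to mono by averaging
#' the channels, with a warning.
#'
#' @param path Path to a `.wav` file.
#' @return A `waveform` object: list with `samples` (numeric vector in
#'   `[-1, 1]`) and `rate` (samples per second).
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) abort(paste0("WAV file not found: ", path))
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) abort("not a RIFF/WAVE file (missing 'RIFF' magic)")
  invisible(readBin(con, "integer", size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) abort("not a RIFF/WAVE file (missing 'WAVE' form type)")

  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", size = 4, endian = "little")
    if (id == "fmt ") {
      body <- readBin(con, "raw", n = sz)
      fmt <- list(
        code     = readBin(body[1:2], "integer", size = 2, endian = "little", signed = FALSE),
        channels = readBin(body[3:4], "integer", size = 2, endian = "little", signed = FALSE),
        rate     = readBin(body[5:8], "integer", size = 4, endian = "little"),
        bits     = readBin(body[15:16], "integer", size = 2, endian = "little", signed = FALSE)
      )
    } else if (id == "data") {
      data_raw <- readBin(con, "raw", n = sz)
    } else {
      invisible(readBin(con, "raw", n = sz + (sz %% 2L)))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) abort("incomplete WAV: missing 'fmt ' or 'data' chunk")
  if (!fmt$code %in% c(1L, 3L)) {
    abort(paste0("unsupported WAV codec (format tag ", fmt$code,
                 "); only integer PCM and IEEE float are supported"))
  }
  x <- if (fmt$code == 3L) {
    if (fmt$bits != 32L) abort("only 32-bit float WAV is supported")
    readBin(data_raw, "double", n = length(data_raw) %/% 4L, size = 4, endian = "little")
  } else if (fmt$bits == 16L) {
    readBin(data_raw, "integer", n = length(data_raw) %/% 2L, size = 2,
            endian = "little", signed = TRUE) / 2^15
  } else if (fmt$bits == 24L) {
    b <- as.integer(data_raw)
    n <- length(b) %/% 3L
    i <- 3L * seq_len(n)
    v <- b[i - 2L] + 256L * b[i - 1L] + 65536L * b[i]
    v <- ifelse(v >= 2^23, v - 2^24, v)
    v / 2^23
  } else {
    abort(paste0("unsupported PCM bit depth: ", fmt$bits,
                 " (16- and 24-bit integer and 32-bit float are supported)"))
  }
  if (fmt$channels > 1L) {
    warn(paste0("downmixing ", fmt$channels, "-channel audio to mono by averaging"))
    nfr <- length(x) %/% fmt$channels
    x <- colMeans(matrix(x[seq_len(nfr * fmt$channels)], nrow = fmt$channels))
  }
  waveform(x, fmt$rate)
}

#' Construct a waveform object
#'
#' @param samples Numeric amplitude vector, nominally in `[-1, 1]`.
#' @param rate Sampling rate in Hz.
#' @return A `waveform` object.
#' @export
waveform <- function(samples, rate) {
  stopifnot(is.numeric(samples), is.numeric(rate), rate > 0)
  structure(list(samples = as.numeric(samples), rate = rate), class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform> %d samples @ %g Hz (%.3f s)\n",
              length(x$samples), x$rate, length(x$samples) / x$rate))
  invisible(x)
}

#' Write a PCM WAV file
#'
#' @param w A [waveform()] object.
#' @param path Output path.
#' @param bit_depth Either 16 or 24 (integer PCM).
#' @return Invisibly, `path`.
#' @export
write_wav <- function(w, path, bit_depth = 24) {
  stopifnot(inherits(w, "waveform"), bit_depth %in% c(16, 24))
  x <- pmin(pmax(w$samples, -1), 1)
  bytes_per <- bit_depth / 8
  n <- length(x)
  data_size <- n * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")            # PCM
  writeBin(1L, con, size = 2, endian = "little")            # mono
  writeBin(as.integer(w$rate), con, size = 4, endian = "little")
  writeBin(as.integer(w$rate * bytes_per), con, size = 4, endian = "little")
  writeBin(as.integer(bytes_per), con, size = 2, endian = "little")
  writeBin(as.integer(bit_depth), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (bit_depth == 16) {
    v <- as.integer(round(x * (2^15 - 1)))
    writeBin(v, con, size = 2, endian = "little")
  } else {
    v <- as.integer(round(x * (2^23 - 1)))
    v <- ifelse(v < 0, v + 2^24, v)
    b <- rbind(v %% 256L, (v %/% 256L) %% 256L, (v %/% 65536L) %% 256L)
    writeBin(as.raw(b), con)
  }
  invisible(path)
}

#' Praat-style intensity contour
#'
#' Computes windowed mean-square energy in dB along the recording, the
#' contour from which each call's maximum-intensity peak is read. Each frame
#' value is \eqn{10 \log_{10}} of the window-weighted mean squared amplitude
#' divided by \eqn{(2\times10^{-5})^2}, i.e. full-scale amplitude 1.0 is
#' referenced to 20 micro-Pascal as Praat does, so a unit-amplitude sinusoid
#' sits at about 91 dB.
#'
#' The default analysis window is a Kaiser window (beta = 20) with effective
#' duration `3.2/min_pitch` (physical duration twice that), stepped by
#' `0.8/min_pitch` — the Praat defaults at `min_pitch = 100` Hz: a 32 ms
#' effective window every 8 ms. A Hann window of duration `3.2/min_pitch`
#' is available as an alternative.
#'
#' @param w A [waveform()] object.
#' @param min_pitch Minimum pitch in Hz controlling window length
#'   (default 100).
#' @param time_step Frame step in seconds (default `0.8/min_pitch`).
#' @param window `"kaiser"` (default) or `"hann"`.
#' @param silence_floor dB value assigned to frames whose window contains
#'   only zeros (default -300), keeping the contour finite.
#' @return An `intensity_contour` tibble with columns `time` (frame centre,
#'   seconds) and `intensity` (dB); frame step and window settings are
#'   attached as attributes.
#' @export
intensity_contour <- function(w, min_pitch = 100, time_step = 0.8 / min_pitch,
                              window = c("kaiser", "hann"),
                              silence_floor = -300) {
  stopifnot(inherits(w, "waveform"), min_pitch > 0, time_step > 0)
  window <- match.arg(window)
  dur <- length(w$samples) / w$rate
  eff_len <- 3.2 / min_pitch
  win_len <- if (window == "kaiser") 2 * eff_len else eff_len
  if (dur < win_len) {
    abort(sprintf(paste0(
      "recording (%.3f s) is shorter than one analysis window (%.3f s); ",
      "raise min_pitch or provide a longer recording"), dur, win_len))
  }
  nwin <- max(2L, round(win_len * w$rate))
  wts <- if (window == "kaiser") signal::kaiser(nwin, beta = 20) else {
    0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = nwin))
  }
  wts <- wts / sum(wts)
  half <- (nwin - 1) / 2 / w$rate
  centers <- seq(half, dur - half, by = time_step)
  x2 <- w$samples^2
  starts <- pmax(1L, pmin(length(x2) - nwin + 1L,
                          as.integer(round(centers * w$rate - (nwin - 1) / 2)) + 1L))
  vals <- vapply(starts, function(s) {
    sum(wts * x2[s:(s + nwin - 1L)])
  }, numeric(1))
  db <- ifelse(vals <= 0, silence_floor,
               pmax(silence_floor, 10 * log10(vals / 4e-10)))
  out <- tibble(time = centers, intensity = db)
  class(out) <- c("intensity_contour", class(out))
  attr(out, "time_step") <- time_step
  attr(out, "min_pitch") <- min_pitch
  attr(out, "window") <- window
  attr(out, "silence_floor") <- silence_floor
  out
}

#' Maximum-intensity peak within a call interval
#'
#' Finds the time of the maximum intensity-contour value among frames whose
#' centre lies in `[onset, offset)`. Ties are broken in favour of the
#' earliest frame, so the result is deterministic.
#'
#' @param contour An [intensity_contour()] tibble.
#' @param onset,offset Interval bounds in seconds, `onset < offset`.
#' @return A list with `peak_time` (seconds) and `peak_level` (dB).
#' @export
peak_in_interval <- function(contour, onset, offset) {
  stopifnot(inherits(contour, "intensity_contour"), onset < offset)
  sel <- which(contour$time >= onset & contour$time < offset)
  if (length(sel) == 0L) {
    abort(sprintf(paste0(
      "no intensity frame inside [%.4f, %.4f); ",
      "use a smaller time_step when computing the contour"), onset, offset))
  }
  k <- sel[which.max(contour$intensity[sel])]
  list(peak_time = contour$time[k], peak_level = contour$intensity[k])
}

#' Locate the intensity peak of every call
#'
#' Augments a call table with each call's maximum-intensity peak time and
#' level read from the intensity contour.
#'
#' @param calls Tibble with `onset`/`offset` columns (seconds), e.g. from
#'   [select_calls()].
#' @param contour An [intensity_contour()] tibble covering the calls.
#' @return `calls` with added columns `peak_time` (s) and `peak_level` (dB),
#'   sorted by onset.
#' @export
call_peaks <- function(calls, contour) {
  stopifnot(is.data.frame(calls), all(c("onset", "offset") %in% names(calls)))
  calls <- calls[order(calls$onset), , drop = FALSE]
  pk <- map2(calls$onset, calls$offset, function(a, b) peak_in_interval(contour, a, b))
  calls$peak_time <- map_dbl(pk, "peak_time")
  calls$peak_level <- map_dbl(pk, "peak_level")
  tibble::as_tibble(calls)
}
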
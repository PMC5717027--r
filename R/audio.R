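#' Read a PCM WAV file
#'
#' Minimal RIFF/WAVE reader for uncompressed PCM (8/16/24/32-bit integer)
#' and IEEE float32 data. Multi-channel audio is averaged to mono; the
#' native sampling rate is preserved.
#'
#' @param path Path to a `.wav` file.
#' @return A list of class `waveform` with `samples` (numeric in
#'   `[-1, 1]`) and `rate` (Hz).
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  readBin(con, "integer", 1L, size = 4L, endian = "little")
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE")) {
    stop(errorCondition(paste0("not a RIFF/WAVE file: ", path),
                        class = c("memoryfoam_format", "error")))
  }
  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_raw <- readBin(con, "raw", sz + sz %% 2L)
      fmt <- list(
        audio_format = readBin(fmt_raw[1:2], "integer", 1L, 2L, signed = FALSE, endian = "little"),
        channels = readBin(fmt_raw[3:4], "integer", 1L, 2L, signed = FALSE, endian = "little"),
        rate = readBin(fmt_raw[5:8], "integer", 1L, 4L, endian = "little"),
        bits = readBin(fmt_raw[15:16], "integer", 1L, 2L, signed = FALSE, endian = "little"))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
      if (sz %% 2L == 1L) readBin(con, "raw", 1L)
    } else {
      readBin(con, "raw", sz + sz %% 2L)
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    stop(errorCondition("missing fmt or data chunk in WAV file",
                        class = c("memoryfoam_format", "error")))
  }
  bytes <- fmt$bits %/% 8L
  n <- length(data_raw) %/% bytes
  x <- if (fmt$audio_format == 3L && fmt$bits == 32L) {
    readBin(data_raw, "double", n, size = 4L, endian = "little")
  } else if (fmt$audio_format == 1L && fmt$bits == 8L) {
    (readBin(data_raw, "integer", n, size = 1L, signed = FALSE) - 128) / 128
  } else if (fmt$audio_format == 1L && fmt$bits == 16L) {
    readBin(data_raw, "integer", n, size = 2L, signed = TRUE, endian = "little") / 32768
  } else if (fmt$audio_format == 1L && fmt$bits == 24L) {
    b <- as.integer(data_raw)
    i <- seq(1L, length(b) - 2L, by = 3L)
    v <- b[i] + 256L * b[i + 1L] + 65536L * b[i + 2L]
    ifelse(v >= 2^23, v - 2^24, v) / 2^23
  } else if (fmt$audio_format == 1L && fmt$bits == 32L) {
    readBin(data_raw, "integer", n, size = 4L, endian = "little") / 2^31
  } else {
    stop(errorCondition(sprintf("unsupported WAV encoding (format %d, %d bit)",
                                fmt$audio_format, fmt$bits),
                        class = c("memoryfoam_format", "error")))
  }
  if (fmt$channels > 1L) {
    x <- x[seq_len((length(x) %/% fmt$channels) * fmt$channels)]
    x <- rowMeans(matrix(x, ncol = fmt$channels, byrow = TRUE))
  }
  structure(list(samples = x, rate = fmt$rate), class = "waveform")
}

#' Write a mono waveform as 16-bit PCM WAV
#'
#' @param samples Numeric samples in `[-1, 1]` (clipped otherwise).
#' @param rate Sampling rate, Hz.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, rate, path) {
  check_finite(samples, "samples")
  pcm <- as.integer(round(pmin(pmax(samples, -1), 1) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_size <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + data_size, con, size = 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little")           # PCM
  writeBin(1L, con, size = 2L, endian = "little")           # mono
  writeBin(as.integer(rate), con, size = 4L, endian = "little")
  writeBin(as.integer(rate) * 2L, con, size = 4L, endian = "little")
  writeBin(2L, con, size = 2L, endian = "little")
  writeBin(16L, con, size = 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, size = 4L, endian = "little")
  writeBin(pcm, con, size = 2L, endian = "little")
  invisible(path)
}

#' Synthesise a pure-tone melody waveform (test fixture)
#'
#' Renders a [melody_spec()] as a phase-continuous sinusoid at the (jittered)
#' note frequencies — a synthetic stand-in for a recorded performance, used
#' to exercise the audio pipeline end to end.
#'
#' @param spec A [melody_spec()].
#' @param rate Audio sampling rate, Hz (default 8000).
#' @param amplitude Peak amplitude in `[0, 1]`.
#' @param seed Jitter seed (jitter is drawn once per beat here).
#' @return A `waveform` (list of `samples`, `rate`).
#' @export
synth_melody_waveform <- function(spec = melody_spec(), rate = 8000,
                                  amplitude = 0.8, seed = NULL) {
  beats <- rep(spec$sequence, spec$reps)
  f_beat <- unname(spec$tuning[beats])
  if (spec$jitter_sd > 0) {
    f_beat <- f_beat + with_seed(seed, stats::rnorm(length(f_beat), sd = spec$jitter_sd))
  }
  spb <- round(spec$beat * rate)
  freq <- rep(f_beat, each = spb)
  phase <- cumsum(2 * pi * freq / rate)
  structure(list(samples = amplitude * sin(phase), rate = rate),
            class = "waveform")
}

#' Track the dominant frequency with a sliding Fourier window
#'
#' Applies a short-time Fourier transform with a Hann (optionally
#' rectangular) window of duration `window` seconds, sliding by `hop`
#' seconds, and extracts for each frame the frequency of the highest
#' spectral peak inside `band`, refined by parabolic interpolation over the
#' three bins around the peak. Silent (all-zero) frames yield `NA`.
#'
#' @param waveform A `waveform` from [read_wav()] or
#'   [synth_melody_waveform()].
#' @param window Window duration, seconds (default 0.75, about one beat).
#' @param hop Hop between frames, seconds (default 0.125, i.e. an 8 Hz
#'   track).
#' @param band Frequency search band `c(lo, hi)` in Hz, rejecting DC and
#'   high-frequency artifacts.
#' @param window_fn `"hann"` or `"rect"`.
#' @return An object of class `pitch_track`: list with `freqs` (Hz, `NA` for
#'   silent frames), `times` (frame centers, s), `rate` (`1/hop`).
#' @export
track_peak_frequency <- function(waveform, window = 0.75, hop = 0.125,
                                 band = c(80, 2000),
                                 window_fn = c("hann", "rect")) {
  window_fn <- match.arg(window_fn)
  fs <- waveform$rate
  x <- waveform$samples
  nw <- round(window * fs)
  if (nw < 2L) stop_invalid("window too short: needs window * rate >= 2")
  if (hop <= 0) stop_invalid("hop must be > 0")
  nh <- max(1L, round(hop * fs))
  w <- if (window_fn == "hann") signal::hanning(nw) else rep(1, nw)
  starts <- seq(1L, length(x) - nw + 1L, by = nh)
  if (length(starts) == 0L) stop_invalid("waveform shorter than one window")
  freq_axis <- (0:(nw - 1L)) * fs / nw
  in_band <- which(freq_axis >= band[1L] & freq_axis <= band[2L] &
                     freq_axis <= fs / 2)
  freqs <- vapply(starts, function(s0) {
    seg <- x[s0:(s0 + nw - 1L)]
    if (all(seg == 0)) return(NA_real_)
    mag <- Mod(stats::fft(seg * w))
    kk <- in_band[which.max(mag[in_band])]
    # parabolic refinement on log magnitude over the three bins at the peak
    delta <- 0
    if (kk > 1L && kk < nw) {
      a <- log(mag[kk - 1L] + 1e-300)
      b <- log(mag[kk] + 1e-300)
      cc <- log(mag[kk + 1L] + 1e-300)
      den <- a - 2 * b + cc
      if (is.finite(den) && den < 0) delta <- 0.5 * (a - cc) / den
    }
    (kk - 1L + delta) * fs / nw
  }, numeric(1L))
  structure(list(freqs = freqs,
                 times = (starts - 1L) / fs + window / 2,
                 rate = fs / nh),
            class = "pitch_track")
}

#' @export
print.pitch_track <- function(x, ...) {
  cat(sprintf("<pitch_track> %d frames at %g Hz, %d silent; freq range [%g, %g] Hz\n",
              length(x$freqs), x$rate, sum(is.na(x$freqs)),
              suppressWarnings(min(x$freqs, na.rm = TRUE)),
              suppressWarnings(max(x$freqs, na.rm = TRUE))))
  invisible(x)
}

#' Resample a pitch track to a new uniform rate
#'
#' Nearest-sample resampling onto a uniform grid at `rate` samples per
#' second spanning the original track.
#'
#' @param track A `pitch_track`.
#' @param rate New rate, samples per second.
#' @return A `pitch_track` at the new rate.
#' @export
resample_track <- function(track, rate) {
  if (rate <= 0) stop_invalid("rate must be > 0")
  if (length(track$freqs) == 0L) stop_invalid("empty pitch track")
  if (isTRUE(all.equal(rate, track$rate))) return(track)
  # duration convention: n samples at rate r span n/r seconds
  n_new <- max(1L, round(length(track$freqs) * rate / track$rate))
  t_new <- track$times[1L] + (seq_len(n_new) - 1L) / rate
  idx <- vapply(t_new, function(t) which.min(abs(track$times - t)), integer(1L))
  structure(list(freqs = track$freqs[idx], times = t_new, rate = rate),
            class = "pitch_track")
}

#' Convert a pitch track to a scalar stimulus stream
#'
#' Frames with missing (silent) frequencies are dropped.
#'
#' @param track A `pitch_track`.
#' @return A [stimulus_series()] of pitch values, Hz.
#' @export
track_to_stimulus <- function(track) {
  ok <- !is.na(track$freqs)
  if (!any(ok)) stop_invalid("pitch track contains no voiced frames")
  stimulus_series(track$freqs[ok], dt = 1 / track$rate,
                  t0 = track$times[which(ok)[1L]])
}

#' Delay-embed a pitch track into phrase vectors
#'
#' Codes temporal patterns: at every track sample `t` the embedded vector is
#' \eqn{\eta(t) = (f(t), f(t+\tau), \ldots, f(t+(m-1)\tau))}. For a melody
#' whose notes last \eqn{\tau} seconds this makes each vector an ordered
#' `m`-note phrase. Vectors containing a missing component are dropped.
#'
#' @param track A `pitch_track`.
#' @param delay Component separation \eqn{\tau}, seconds (default 0.75, one
#'   beat).
#' @param dim Embedding dimension `m` (default 4: four-beat phrases).
#' @return A [stimulus_series()] of `m`-dimensional vectors; length
#'   `length(track) - (m-1) * delay * rate`.
#' @export
delay_embed <- function(track, delay = 0.75, dim = 4L) {
  if (delay <= 0) stop_invalid("delay must be > 0")
  dim <- as.integer(dim)
  if (dim < 1L) stop_invalid("dim must be >= 1")
  lag <- round(delay * track$rate)
  n <- length(track$freqs)
  n_out <- n - (dim - 1L) * lag
  if (n_out < 1L) stop_invalid("track too short for this embedding")
  cols <- vapply(0:(dim - 1L), function(j) track$freqs[(1:n_out) + j * lag],
                 numeric(n_out))
  cols <- matrix(cols, nrow = n_out)
  ok <- stats::complete.cases(cols)
  if (!any(ok)) stop_invalid("no complete embedded vectors (all contain silent frames)")
  stimulus_series(cols[ok, , drop = FALSE], dt = 1 / track$rate,
                  t0 = track$times[which(ok)[1L]])
}

#' Write / read a pitch track as CSV
#' @param track A `pitch_track`.
#' @param path File path.
#' @export
write_track_csv <- function(track, path) {
  utils::write.csv(data.frame(time = track$times, freq = track$freqs),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_track_csv
#' @export
read_track_csv <- function(path) {
  df <- utils::read.csv(path)
  dt <- stats::median(diff(df$time))
  structure(list(freqs = df$freq, times = df$time, rate = 1 / dt),
            class = "pitch_track")
}
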
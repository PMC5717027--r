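# write a small stereo PCM16 WAV by hand (the package writer is mono-only)
write_stereo_wav <- function(left, right, rate, path) {
  inter <- as.integer(round(rbind(left, right) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_size <- 2L * length(inter)
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + data_size, con, size = 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little")
  writeBin(2L, con, size = 2L, endian = "little")
  writeBin(as.integer(rate), con, size = 4L, endian = "little")
  writeBin(as.integer(rate) * 4L, con, size = 4L, endian = "little")
  writeBin(4L, con, size = 2L, endian = "little")
  writeBin(16L, con, size = 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, size = 4L, endian = "little")
  writeBin(as.vector(inter), con, size = 2L, endian = "little")
}

tone <- function(freq, dur = 2, rate = 8000, amp = 0.9) {
  structure(list(samples = amp * sin(2 * pi * freq * (0:(dur * rate - 1)) / rate),
                 rate = rate), class = "waveform")
}

test_that("PCM WAV files round-trip and fold stereo to mono", {
  wf <- tone(440, dur = 1)
  f <- withr::local_tempfile(fileext = ".wav")
  write_wav(wf$samples, wf$rate, f)
  rd <- read_wav(f)
  expect_identical(length(rd$samples), 8000L)
  expect_identical(rd$rate, 8000L)
  expect_lt(max(abs(rd$samples - wf$samples)), 1e-3)
  fs <- withr::local_tempfile(fileext = ".wav")
  write_stereo_wav(wf$samples, rev(wf$samples), 8000, fs)
  rds <- read_wav(fs)
  expect_identical(length(rds$samples), 8000L)
  expect_equal(rds$samples, (wf$samples + rev(wf$samples)) / 2, tolerance = 1e-3)
  fbad <- withr::local_tempfile(fileext = ".wav")
  writeLines("not audio", fbad)
  expect_error(read_wav(fbad), class = "memoryfoam_format")
})

test_that("the sliding-window peak tracker recovers pure tone frequencies", {
  tr <- track_peak_frequency(tone(440))
  # window 0.75 s at 8 kHz -> 6000-sample frames, ~1.33 Hz bins; parabolic
  # refinement brings the peak well within 1 Hz
  expect_true(all(abs(tr$freqs - 440) < 1))
  expect_equal(tr$rate, 8)
  # the louder of two tones wins
  two <- tone(392)
  two$samples <- two$samples + 0.3 * sin(2 * pi * 493.88 *
                                           seq_along(two$samples) / 8000)
  expect_true(all(abs(track_peak_frequency(two)$freqs - 392) < 1))
})

test_that("silent frames become missing values and are dropped downstream", {
  wf <- tone(440, dur = 3)
  wf$samples[8001:16000] <- 0            # one silent second
  tr <- track_peak_frequency(wf)
  expect_true(any(is.na(tr$freqs)))
  expect_true(all(abs(tr$freqs[!is.na(tr$freqs)] - 440) < 2))
  stim <- track_to_stimulus(tr)
  expect_false(any(is.na(stim$values)))
  expect_lt(n_samples(stim), length(tr$freqs))
})

test_that("track resampling follows the duration convention", {
  tr <- track_peak_frequency(tone(440, dur = 3))
  expect_identical(resample_track(tr, tr$rate), tr)
  # 24 samples at 1 Hz = 24 s of track -> 192 samples at 8 Hz
  slow <- structure(list(freqs = rep(440, 24), times = 0:23, rate = 1),
                    class = "pitch_track")
  fast <- resample_track(slow, 8)
  expect_identical(length(fast$freqs), 192L)
  expect_true(all(fast$freqs == 440))
  expect_error(resample_track(structure(list(freqs = numeric(0), times = numeric(0),
                                             rate = 8), class = "pitch_track"), 8),
               class = "memoryfoam_invalid_input")
})

test_that("delay embedding forms phrase vectors of time-shifted pitches", {
  tr <- structure(list(freqs = c(392, 440, 494, 392), times = 0.75 * (0:3),
                       rate = 1 / 0.75), class = "pitch_track")
  emb <- delay_embed(tr, delay = 0.75, dim = 4L)
  expect_identical(n_samples(emb), 1L)
  expect_equal(emb$values[1, ], c(392, 440, 494, 392))
  # m = 1 is the identity embedding
  e1 <- delay_embed(tr, delay = 0.75, dim = 1L)
  expect_equal(e1$values[, 1], tr$freqs)
  # 1152 samples at 8 Hz with a 6-sample lag -> 1152 - 3*6 vectors
  stim <- gen_melody(melody_spec(jitter_sd = 0))
  big <- structure(list(freqs = stim$values[, 1], times = stimulus_times(stim),
                        rate = 8), class = "pitch_track")
  expect_identical(n_samples(delay_embed(big, 0.75, 4L)), 1134L)
  expect_error(delay_embed(tr, delay = 10, dim = 4L),
               class = "memoryfoam_invalid_input")
})

test_that("a synthesized jitter-free melody yields three note memories", {
  wf <- synth_melody_waveform(melody_spec(jitter_sd = 0, reps = 2))
  tr <- resample_track(track_peak_frequency(wf), 8)
  stim <- track_to_stimulus(tr)
  L <- learn_landscape(stim, foam_kernel(sqrt(5)))
  floor_d <- 2 * kernel_peak(foam_kernel(sqrt(5))) * stim$dt / L$time
  mins <- find_minima(L, n_starts = 150, seed = 2, min_depth = floor_d)
  expect_identical(nrow(mins), 3L)
  tuning <- sort(c(392, 440, 493.88))
  expect_true(all(abs(sort(mins$x1) - tuning) < 2))
})
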
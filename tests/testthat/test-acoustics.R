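mic <- microphone_model()

test_that("band-pass matches the frequency-response oracle", {
  fs <- 100000
  for (f in c(1000, sqrt(140 * 2000))) {
    w <- tone_trial(f, 1, fs, dur = 1)
    y <- bandpass_filter(w)
    mid <- seq(fs * 0.25, fs * 0.75)
    gain_db <- 20 * log10(sqrt(mean(y$samples[mid]^2)) / sqrt(0.5))
    expect_lt(abs(gain_db), 1)
    oracle_db <- 40 * log10(butter_bp_gain(f, 140, 2000))  # two passes
    expect_lt(abs(gain_db - oracle_db), 0.5)
  }
  # stopband: 40 Hz, low/4 and min(2*high, 0.45 fs)
  for (f in c(40, 35, 4000)) {
    w <- tone_trial(f, 1, 20000, dur = 2)
    y <- bandpass_filter(w)
    mid <- seq(20000 * 0.5, 20000 * 1.5)
    atten_db <- -20 * log10(sqrt(mean(y$samples[mid]^2)) / sqrt(0.5))
    expect_gt(atten_db, 20)
    if (f == 40) expect_lt(sqrt(mean(y$samples[mid]^2)), 0.01 * sqrt(0.5))
  }
})

test_that("band-pass edge cases: zeros, bad cutoffs, length", {
  w <- waveform(numeric(2000), 8000)
  expect_equal(bandpass_filter(w)$samples, numeric(2000))
  expect_error(bandpass_filter(waveform(rnorm(1000), 3000)), "Nyquist")
  expect_length(bandpass_filter(tone_trial(500, 1, 8000, dur = 1))$samples,
                8000)
})

test_that("peak segment placement centers, clips, and breaks ties early", {
  fs <- 1000
  x <- numeric(20 * fs)
  x[10 * fs + 1] <- 1   # spike at t = 10 s
  seg <- extract_peak_segment(waveform(x, fs))
  expect_equal(attr(seg, "segment_bounds"), c(7.5 * fs + 1, 12.5 * fs))
  x2 <- numeric(20 * fs); x2[1 * fs + 1] <- -1   # spike at 1 s, negative
  seg2 <- extract_peak_segment(waveform(x2, fs))
  expect_equal(attr(seg2, "segment_bounds"), c(1, 5 * fs))
  x3 <- numeric(20 * fs); x3[c(6 * fs, 14 * fs)] <- 1  # equal maxima
  seg3 <- extract_peak_segment(waveform(x3, fs))
  expect_equal(attr(seg3, "segment_bounds")[1] + 2.5 * fs, 6 * fs)
  expect_error(extract_peak_segment(waveform(rnorm(fs), fs), duration = 5),
               "shorter")
})

test_that("SPL trace implements 20 log10(|Vr|/(P0 Vs)) with rectification", {
  ref <- mic$reference_pressure * mic$voltage_per_pa
  w <- waveform(c(ref, -ref, mic$voltage_per_pa, 0), 1000)
  tr <- spl_trace(w, mic)
  expect_equal(tr[1], 0)
  expect_equal(tr[2], 0)                       # rectified negative
  expect_equal(tr[3], 20 * log10(1 / 2e-5))    # 1 Pa ~ 93.98 dB
  expect_identical(tr[4], -Inf)                # exact zero -> sentinel
})

test_that("trial_max_spl takes the max finite value and rejects silence", {
  expect_equal(trial_max_spl(c(10, 50, 30)), 50)
  expect_equal(trial_max_spl(rep(7.7, 5)), 7.7)
  expect_equal(trial_max_spl(c(-Inf, 12, -Inf)), 12)
  expect_error(trial_max_spl(rep(-Inf, 4)), "silent")
})

test_that("a synthesized 2 Pa burst reads ~99.999 dB through the chain", {
  # 20*log10(2/2e-5) = 99.99913...
  tr <- quick_session(target_spl = 20 * log10(2 / 2e-5), fs = 16000)
  s <- session_spl(tr, mic)
  expect_lt(abs(s$session_spl_db - 99.99913), 0.2)
})

test_that("session_spl is the max over >= 3 trials and permutation-safe", {
  trials <- quick_session(95, fs = 16000)
  s <- session_spl(trials, mic)
  expect_equal(s$session_spl_db, max(s$per_trial_max_db))
  expect_true(all(s$session_spl_db >= s$per_trial_max_db))
  s_perm <- session_spl(trials[c(3, 1, 2)], mic)
  expect_equal(s_perm$session_spl_db, s$session_spl_db)
  expect_error(session_spl(trials[1:2], mic), "three")
})

test_that("SPL covariances: voltage scale, mic sensitivity, idempotence", {
  trials <- quick_session(98, fs = 16000)
  s0 <- session_spl(trials, mic)
  k <- 3.7
  scaled <- lapply(trials, function(w) { w$samples <- w$samples * k; w })
  s1 <- session_spl(scaled, mic)
  expect_equal(s1$session_spl_db - s0$session_spl_db, 20 * log10(k),
               tolerance = 1e-10)
  mic2 <- microphone_model(sensitivity_db = -35 + 6)
  s2 <- session_spl(trials, mic2)
  expect_equal(s2$session_spl_db - s0$session_spl_db, -6, tolerance = 1e-10)
  twice <- lapply(trials, bandpass_filter)
  s3 <- session_spl(twice, mic)
  expect_lt(abs(s3$session_spl_db - s0$session_spl_db), 0.5)
})

test_that("WAV files round-trip in both encodings", {
  x <- sin(2 * pi * 440 * (0:7999) / 8000) * 0.05
  f1 <- tempfile(fileext = ".wav"); f2 <- tempfile(fileext = ".wav")
  write_wav(x, 8000, f1, "pcm16", full_scale_voltage = 0.5)
  r1 <- read_wav(f1, full_scale_voltage = 0.5)
  expect_equal(r1$fs, 8000)
  expect_lt(max(abs(r1$samples - x)), 0.5 / 32767)
  write_wav(x, 8000, f2, "float32")
  r2 <- read_wav(f2)
  expect_lt(max(abs(r2$samples - x)), 1e-7)
})
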
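test_that("truncate_silences shortens long pauses only", {
  fs <- 8000
  tone <- function(dur) sin(2 * pi * 440 * seq(0, dur, by = 1 / fs))
  gap <- function(dur) numeric(round(dur * fs))

  # speech / 1.2 s silence / speech -> silence cut to 0.5 s
  a <- audio_stimulus(c(tone(1), gap(1.2), tone(1)), fs)
  out <- truncate_silences(a, max_pause = 0.5)
  expect_equal(length(a) - length(out), round(0.7 * fs), tolerance = 0.02)

  # no pause longer than 0.5 s -> identity
  b <- audio_stimulus(c(tone(0.5), gap(0.3), tone(0.5)), fs)
  expect_identical(truncate_silences(b)$samples, b$samples)

  # tone / 2 s gap / tone / 0.3 s gap / tone -> exactly 1.5 s removed
  c3 <- audio_stimulus(c(tone(0.7), gap(2), tone(0.7), gap(0.3), tone(0.7)), fs)
  out3 <- truncate_silences(c3)
  expect_equal(length(c3) - length(out3), round(1.5 * fs), tolerance = 0.02)

  # non-silent content preserved in order
  expect_true(all(abs(out3$samples[1:(0.6 * fs)] -
                      c3$samples[1:(0.6 * fs)]) < 1e-12))
  expect_error(truncate_silences(a, max_pause = 0), "positive")
})

test_that("speech high-pass matches the first-order Butterworth response", {
  fs <- 24414
  tt <- seq(0, 2, by = 1 / fs)

  # DC is removed
  dc <- audio_stimulus(rep(0.5, length(tt)), fs)
  out <- highpass_speech(dc, direction = "causal")
  expect_lt(max(abs(out$samples[-(1:fs)])), 0.5 * 1e-4)

  # -3.01 dB at the cutoff
  s1k <- audio_stimulus(sin(2 * pi * 1000 * tt), fs)
  out1k <- highpass_speech(s1k, direction = "anticausal")
  mid <- out1k$samples[round(0.5 * fs):round(1.5 * fs)]
  gain_db <- 20 * log10(max(abs(mid)))
  expect_equal(gain_db, -3.01, tolerance = 0.1)

  # near-unity in the passband (analytic |H| at 8 kHz, fs 24414)
  s8k <- audio_stimulus(sin(2 * pi * 8000 * tt), fs)
  out8k <- highpass_speech(s8k, direction = "anticausal")
  mid8 <- out8k$samples[round(0.5 * fs):round(1.5 * fs)]
  bf <- signal::butter(1, 1000 / (fs / 2), type = "high")
  h_analytic <- speechABR::iir_magnitude(bf$b, bf$a, 8000, fs)
  expect_equal(20 * log10(max(abs(mid8))), 20 * log10(h_analytic),
               tolerance = 0.1)
  expect_lt(abs(20 * log10(h_analytic)), 0.5)

  expect_error(highpass_speech(s1k, cutoff = 13000), "Nyquist")
})

test_that("normalize_rms is a pure rescale to the target", {
  fs <- 24414
  tt <- seq(0, 1, by = 1 / fs)
  sine <- audio_stimulus(sin(2 * pi * 500 * tt), fs)
  out <- normalize_rms(sine)
  expect_equal(sqrt(mean(out$samples^2)), 0.01, tolerance = 1e-9)
  # gain for a unit sinusoid is 0.01 * sqrt(2)
  expect_equal(max(abs(out$samples)) / max(abs(sine$samples)),
               0.01 * sqrt(2), tolerance = 1e-4)
  # already at target -> unchanged
  expect_equal(normalize_rms(out)$samples, out$samples, tolerance = 1e-12)
  # arbitrary noise burst
  set.seed(42)
  noise <- audio_stimulus(rnorm(10000) * seq(0, 1, length.out = 10000), fs)
  expect_equal(sqrt(mean(normalize_rms(noise)$samples^2)), 0.01,
               tolerance = 1e-9)
  expect_error(normalize_rms(audio_stimulus(numeric(100) + 0, fs)), "zero")
})

test_that("section_epochs overlaps, fades, and counts novel content", {
  fs <- 1000
  a <- audio_stimulus(rnorm(124 * fs), fs)
  ep <- section_epochs(a, epoch_dur = 64, fade_dur = 1, overlap_dur = 4)
  expect_length(ep$epochs, 2)
  expect_equal(ep$novel_dur, 60)

  # shared content: epoch 1's last 4 s pre-fade == epoch 2's first 4 s pre-fade
  n_ep <- 64 * fs
  shared_src <- a$samples[(60 * fs + 1):(64 * fs)]
  # region of epoch 2 past its fade-in still inside the overlap
  idx2 <- (1 * fs + 1):(4 * fs)
  expect_equal(ep$epochs[[2]]$samples[idx2], shared_src[idx2], tolerance = 1e-12)

  # fades: first and last samples heavily attenuated
  expect_lt(abs(ep$epochs[[1]]$samples[1]), abs(a$samples[1]) + 1e-6)
  w_first <- ep$epochs[[1]]$samples[1] / a$samples[1]
  expect_lt(w_first, 0.01)

  # overlap 0 -> plain partition
  ep0 <- section_epochs(a, epoch_dur = 62, fade_dur = 0, overlap_dur = 0)
  expect_length(ep0$epochs, 2)
  expect_identical(ep0$epochs[[1]]$samples, a$samples[1:(62 * fs)])
  expect_error(section_epochs(a, epoch_dur = 1, fade_dur = 0.6), "fades")
})

test_that("click trains have the right timing statistics", {
  # periodic: floor(rate * duration) clicks at exact multiples of 1/rate
  per <- make_click_train(rate = 44.1, duration = 1, timing = "periodic")
  expect_length(per$click_times, 44)
  expect_equal(per$click_times, (0:43) / 44.1, tolerance = 1e-12)
  expect_equal(diff(per$click_times), rep(1 / 44.1, 43), tolerance = 1e-12)

  # 20 repetitions of 30 s at 44.1/s -> 26,460 expected clicks
  expect_equal(floor(44.1 * 30) * 20, 26460)

  # poisson: reproducible under seed; count near rate * duration
  p1 <- make_click_train(duration = 30, timing = "poisson", seed = 11)
  p2 <- make_click_train(duration = 30, timing = "poisson", seed = 11)
  expect_identical(p1$click_times, p2$click_times)
  expect_true(all(p1$click_times >= 0 & p1$click_times < 30))

  # Monte-Carlo: mean count within 3 SE of 1323; Fano factor near 1
  set.seed(99)
  counts <- replicate(400, length(make_click_train(duration = 30,
                                                   timing = "poisson")$click_times))
  se <- sqrt(1323 / 400)
  expect_lt(abs(mean(counts) - 1323), 3 * se)
  expect_gt(var(counts) / mean(counts), 0.8)
  expect_lt(var(counts) / mean(counts), 1.25)
})

test_that("rendered click audio uses ppe-SPL calibration and 2-sample width", {
  tr <- make_click_train(rate = 44.1, duration = 2, timing = "poisson",
                         seed = 5)
  # two samples at 24,414 Hz last 81.9 us, as close to the standard
  # 100-us click as this sampling rate allows
  expect_equal(2 / tr$fs_audio * 1e6, 82, tolerance = 0.5)

  au <- render_click_audio(tr)
  nz <- which(au$samples != 0)
  expect_length(nz, 2 * length(tr$click_times))
  # rarefaction: negative-going, peak at the 1-kHz-tone peak amplitude
  expect_true(all(au$samples[nz] < 0))
  expect_equal(max(abs(au$samples)), sqrt(2) * 0.01, tolerance = 1e-12)

  # single click at t = 0 occupies exactly the first two samples
  one <- make_click_train(rate = 1, duration = 1, timing = "periodic",
                          polarity = "condensation")
  au1 <- render_click_audio(one)
  expect_identical(which(au1$samples != 0), 1:2)
})

test_that("speech regressor splits polarity losslessly before resampling", {
  # pre-resampling rectification: [1, -2, 3] -> pos [1,0,3], neg [0,2,0]
  x <- c(1, -2, 3)
  expect_equal(pmax(x, 0), c(1, 0, 3))
  expect_equal(pmax(-x, 0), c(0, 2, 0))

  fs_a <- 24414; fs_e <- 10000
  tt <- seq(0, 2, by = 1 / fs_a)
  sine <- audio_stimulus(0.01 * sqrt(2) * sin(2 * pi * 300 * tt), fs_a)
  reg <- make_regressor_speech(sine, fs_e)
  expect_s3_class(reg, "abr_regressor")
  expect_true(all(reg$pos[[1]] >= 0) && all(reg$neg[[1]] >= 0))
  # symmetric signal: branch means agree within 1%
  expect_equal(mean(reg$pos[[1]]), mean(reg$neg[[1]]), tolerance = 0.01)

  # pure positive signal -> neg branch ~ 0
  posonly <- audio_stimulus(abs(sin(2 * pi * 300 * tt)) * 0.01, fs_a)
  regp <- make_regressor_speech(posonly, fs_e)
  expect_lt(max(regp$neg[[1]]), 1e-6 * max(regp$pos[[1]]) + 1e-12)

  # pos - neg reconstructs the band-limited signed audio (r > 0.99)
  a <- make_speechlike_audio(2, seed = 3)
  reg2 <- make_regressor_speech(a, fs_e)
  signed <- resample_waveform(a$samples, a$fs, fs_e)
  expect_gt(cor(reg2$pos[[1]] - reg2$neg[[1]], signed), 0.99)

  expect_error(make_regressor_speech(sine, fs_eeg = 30000), "below")
})

test_that("impulse-train regressor uses nearest-index placement, unit height", {
  tr <- make_click_train(rate = 10, duration = 1, timing = "periodic")
  tr$click_times <- c(0.1, 0.10005, 0.5)
  expect_warning(reg <- make_regressor_clicks(tr, fs_eeg = 10000),
                 "collided")
  v <- reg$pos[[1]]
  # 0.1 s -> index 1001 (1-based); 0.10005 rounds half-to-even to the same
  expect_equal(which(v == 1), c(1001, 5001))
  expect_true(all(v %in% c(0, 1)))
  expect_identical(reg$pos, reg$neg)

  # sum equals number of distinct mapped clicks
  tr2 <- make_click_train(rate = 44.1, duration = 5, timing = "poisson",
                          seed = 2)
  reg2 <- make_regressor_clicks(tr2, fs_eeg = 10000)
  expect_equal(sum(reg2$pos[[1]]),
               length(unique(round(tr2$click_times * 10000))))
})

test_that("poisson click audio has a flat expected spectrum", {
  set.seed(7)
  acc <- 0
  for (i in 1:8) {
    tr <- make_click_train(rate = 200, duration = 4, timing = "poisson",
                           fs_audio = 8000, click_width_samples = 1L)
    au <- render_click_audio(tr)
    acc <- acc + Mod(fft(au$samples - mean(au$samples)))^2
  }
  f <- (seq_along(acc) - 1) * 8000 / length(acc)
  sel <- f > 100 & f < 3900
  bands <- cut(f[sel], 12)
  bp <- tapply(acc[sel], bands, mean)
  # expected power flat across bands within a factor ~1.5 (Monte-Carlo)
  expect_lt(max(bp) / min(bp), 1.5)
})
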
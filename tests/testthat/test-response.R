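test_that("deconvolution is an identity for single-impulse regressors", {
  fs <- 2000
  set.seed(11)
  kern <- abr_kernel(fs, max_lag_ms = 50)
  nk <- length(kern$amplitude)
  n <- 2 * fs
  m <- 600                       # impulse position, windows fit inside
  y <- numeric(n)
  y[m:(m + nk - 1)] <- kern$amplitude
  x <- numeric(n); x[m] <- 1
  ep <- epochs_from_matrix(matrix(y, 1), fs)
  resp <- deconvolve(ep, abr_regressor(list(x), list(x), fs), lags = c(-50, 60))
  rec <- resp$amplitude[resp$lags_ms >= 0 & resp$lags_ms <= 50]
  expect_lt(max(abs(rec - kern$amplitude)), 1e-6 * max(abs(kern$amplitude)))
  # nothing at negative lags
  expect_rms_lt(resp$amplitude[resp$lags_ms < -5], 1e-9)
})

test_that("impulse deconvolution equals the click-triggered average exactly", {
  # sweep-style data: one click per epoch (flat per-epoch regressor spectrum,
  # the condition under which the equivalence is exact), plus noise
  fs <- 10000
  set.seed(12)
  kern <- abr_kernel(fs, max_lag_ms = 50)
  n <- fs                        # 1-s epochs
  n_ep <- 12
  lags <- c(-150, 350)
  dat <- matrix(rnorm(n_ep * n, sd = 0.5), n_ep, n)
  clicks <- vector("list", n_ep)
  for (k in seq_len(n_ep)) {
    m <- sample(2000:5000, 1)
    dat[k, m:(m + length(kern$amplitude) - 1)] <-
      dat[k, m:(m + length(kern$amplitude) - 1)] + kern$amplitude
    clicks[[k]] <- m
  }
  ep <- epochs_from_matrix(dat, fs)
  reg <- lapply(clicks, function(m) { v <- numeric(n); v[m] <- 1; v })
  reg <- abr_regressor(reg, reg, fs, kind = "impulse_train")
  dec <- deconvolve(ep, reg, lags)
  cta <- click_triggered_average(ep, reg, lags)
  expect_lt(max(abs(dec$amplitude - cta$amplitude)), 1e-9)
})

test_that("poisson-train deconvolution matches the sweep average closely", {
  fs <- 10000
  set.seed(13)
  kern <- abr_kernel(fs, max_lag_ms = 50)
  n_ep <- 4; dur <- 10
  n <- dur * fs
  trains <- lapply(1:n_ep, function(i)
    make_click_train(duration = dur, timing = "poisson", seed = 130 + i))
  # occasional index collisions are expected at this density
  reg <- suppressWarnings(make_regressor_clicks(trains, fs))
  dat <- matrix(rnorm(n_ep * n, sd = 0.2), n_ep, n)
  for (k in seq_len(n_ep)) {
    dat[k, ] <- dat[k, ] +
      speechABR:::conv_linear(reg$pos[[k]], kern$amplitude)[1:n]
  }
  ep <- epochs_from_matrix(dat, fs)
  dec <- deconvolve(ep, reg, lags = c(-20, 50))
  cta <- click_triggered_average(ep, reg, lags = c(-20, 50))
  i <- dec$lags_ms >= 0 & dec$lags_ms <= 20
  expect_gt(cor(dec$amplitude[i], cta$amplitude[i]), 0.95)
  # and the deconvolution recovers the generating kernel itself
  expect_gt(cor(dec$amplitude[i],
                kern$amplitude[kern$lags_ms <= 20]), 0.99)
})

test_that("response scales with EEG gain and inversely with regressor gain", {
  fs <- 2000
  set.seed(14)
  x <- abs(rnorm(4 * fs))
  kern <- abr_kernel(fs, max_lag_ms = 50)
  y <- speechABR:::conv_linear(x, kern$amplitude)[seq_along(x)]
  base <- deconvolve(epochs_from_matrix(matrix(y, 1), fs),
                     abr_regressor(list(x), list(x), fs), lags = c(-20, 50))
  up <- deconvolve(epochs_from_matrix(matrix(3 * y, 1), fs),
                   abr_regressor(list(x), list(x), fs), lags = c(-20, 50))
  expect_equal(up$amplitude, 3 * base$amplitude, tolerance = 1e-10)
  dn <- deconvolve(epochs_from_matrix(matrix(y, 1), fs),
                   abr_regressor(list(2 * x), list(2 * x), fs),
                   lags = c(-20, 50))
  expect_equal(dn$amplitude, base$amplitude / 2, tolerance = 1e-10)
})

test_that("white-noise regressor recovers a long kernel at -20 dB per sample", {
  fs <- 2000
  set.seed(15)
  nk <- 500
  kern <- exp(-(1:nk) / 150) * sin(2 * pi * (1:nk) * 7 / nk)
  kern <- kern / sqrt(sum(kern^2))      # unit-energy kernel
  n <- 30 * fs; n_ep <- 16
  dat <- matrix(0, n_ep, n)
  xs <- vector("list", n_ep)
  for (k in seq_len(n_ep)) {
    x <- rnorm(n)
    sig <- speechABR:::conv_linear(x, kern)[1:n]
    dat[k, ] <- sig + rnorm(n, sd = 10 * sd(sig))   # -20 dB per sample
    xs[[k]] <- x
  }
  # signed white-noise regressor, constructed directly (the non-negativity
  # constraint of abr_regressor() applies to rectified drives, not here)
  reg <- structure(list(pos = xs, neg = xs, fs_eeg = fs,
                        kind = "rectified_speech"), class = "abr_regressor")
  ep <- epochs_from_matrix(dat, fs)
  resp <- deconvolve(ep, reg, lags = c(-50, 260))
  i <- resp$lags_ms > 0 & resp$lags_ms <= 250
  expect_gt(cor(resp$amplitude[i], kern[1:sum(i)]), 0.95)
})

test_that("noise floor in the response shrinks with total epochs", {
  fs <- 2000
  set.seed(16)
  x <- abs(rnorm(4 * fs))
  noise_rms_at <- function(n_ep) {
    dat <- matrix(rnorm(n_ep * length(x), sd = 5), n_ep)
    reg <- abr_regressor(rep(list(x), n_ep), rep(list(x), n_ep), fs)
    r <- deconvolve(epochs_from_matrix(dat, fs), reg, lags = c(-150, 350))
    sqrt(mean(r$amplitude[r$lags_ms >= -125 & r$lags_ms <= -10]^2))
  }
  r4 <- mean(replicate(6, noise_rms_at(4)))
  r16 <- mean(replicate(6, noise_rms_at(16)))
  expect_equal(r4 / r16, 2, tolerance = 0.4)   # 1/sqrt(E) law
})

test_that("postfilter views and identity behave as specified", {
  fs <- 10000
  # slow kernel (< 200 Hz content): 2-kHz filtering changes it < 1%
  slow <- abr_kernel(fs, latencies_ms = 30, amplitudes_uV = 1,
                     widths_ms = 6, freqs_hz = 30, max_lag_ms = 100)
  resp <- kernel_as_response(slow)
  f <- postfilter_response(resp, direction = "zerophase")
  expect_lt(sqrt(mean((f$amplitude - resp$amplitude)^2)) /
            sqrt(mean(resp$amplitude^2)), 0.01)

  # 20-Hz low-pass abolishes Wave V (no 5-7 ms peak above flanks)
  k <- kernel_as_response(abr_kernel(fs))
  sharp <- find_wave_v(postfilter_response(k, lp = 2000))
  blurred <- postfilter_response(k, lp = 20)
  sel <- blurred$lags_ms >= 5 & blurred$lags_ms <= 7
  expect_lt(max(blurred$amplitude[sel]), 0.3 * sharp$amplitude_uV)

  # omitted low-pass is the identity
  expect_identical(postfilter_response(k, lp = NULL), k)
})

test_that("condition averaging is a pointwise weighted mean", {
  fs <- 10000
  a <- kernel_as_response(abr_kernel(fs))
  expect_equal(combine_conditions(list(a, a))$amplitude, a$amplitude)
  b <- a; b$amplitude <- -a$amplitude
  expect_equal(combine_conditions(list(a, b))$amplitude,
               rep(0, length(a$amplitude)))
  w <- combine_conditions(list(a, b), weights = c(3, 1))
  expect_equal(w$amplitude, a$amplitude / 2, tolerance = 1e-12)
})

test_that("g_n follows the cohort formula and recovers a known ratio", {
  fs <- 10000
  base <- kernel_as_response(abr_kernel(fs))
  expect_equal(compute_gn(list(base), list(base))$g_n, 1)

  small <- base; small$amplitude <- base$amplitude / 28.2
  expect_equal(compute_gn(list(base), list(small))$g_n, 28.2,
               tolerance = 1e-9)

  # simulated cohort: per-subject gains scattered around a known ratio
  set.seed(17)
  true_ratio <- 28.2
  clicks <- speech <- vector("list", 10)
  for (i in 1:10) {
    g_subj <- exp(rnorm(1, 0, 0.2))
    clicks[[i]] <- base
    clicks[[i]]$amplitude <- base$amplitude * g_subj
    speech[[i]] <- base
    speech[[i]]$amplitude <- base$amplitude * g_subj / true_ratio *
      exp(rnorm(1, 0, 0.05))
  }
  gn <- compute_gn(clicks, speech)
  expect_equal(gn$g_n, true_ratio, tolerance = 0.05 * true_ratio)
  norm <- apply_gn(speech[[1]], gn)
  expect_true(norm$normalized)
  expect_equal(norm$amplitude, speech[[1]]$amplitude * gn$g_n)

  zero <- base; zero$amplitude <- base$amplitude * 0
  expect_error(compute_gn(list(base), list(zero)), "zero")
})

test_that("traditional click ABR epochs, rejects, and averages correctly", {
  fs <- 10000
  rate <- 44.1
  # window ends at -3 + 1000/44.1 = 19.675 ms, printed as 19.7
  expect_equal(-3 + 1000 / rate, 19.7, tolerance = 0.05)

  set.seed(18)
  kern <- abr_kernel(fs, max_lag_ms = 15)
  dur <- 20
  train <- make_click_train(rate = rate, duration = dur, timing = "periodic")
  reg <- make_regressor_clicks(train, fs)
  sig <- speechABR:::conv_linear(reg$pos[[1]], kern$amplitude)
  pot <- c(numeric(fs), sig[1:(dur * fs)], numeric(fs)) +
    rnorm((dur + 2) * fs, sd = 1)
  # inject large biphasic artifacts into 10% of sweeps
  click_idx <- fs + round(train$click_times * fs) + 1
  bad <- seq(5, length(click_idx), by = 10)
  for (b in bad) pot[click_idx[b] + 50:51] <- c(200, -200)
  rec <- eeg_recording(pot, fs, markers = fs + 1L)
  abr <- average_abr_traditional(rec, train)
  expect_equal(abr$provenance$n_rejected, length(bad))
  expect_equal(max(abr$lags_ms), 19.6, tolerance = 0.1)
  expect_equal(min(abr$lags_ms), -3)
  # the average contains the kernel's Wave V (150-Hz high-pass reshapes the
  # waveform, but the 5-7 ms peak survives)
  wv <- find_wave_v(abr)
  expect_equal(wv$latency_ms, 6.5, tolerance = 0.8)

  set.seed(20)
  rec_allbad <- eeg_recording(rnorm(5000, sd = 500), fs, markers = 1L)
  expect_error(
    average_abr_traditional(rec_allbad,
      make_click_train(rate = 44.1, duration = 0.1, timing = "periodic")),
    "rejected")
})

test_that("zeroing plus g_r leaves the derived amplitude unbiased", {
  fs <- 2000
  set.seed(19)
  x <- abs(rnorm(8 * fs))
  kern <- abr_kernel(fs, max_lag_ms = 50)
  y <- speechABR:::conv_linear(x, kern$amplitude)[seq_along(x)]
  n_ep <- 6
  ep <- epochs_from_matrix(matrix(rep(y, n_ep), n_ep, byrow = TRUE), fs)
  ep$g_r_applied <- FALSE
  # plant excursions in half the epochs (threshold tiny to force zeroing)
  for (k in 1:3) ep$data[k, 4000 + 500 * k] <- 1e4
  z <- suppressWarnings(zero_excursions(ep, threshold = 1e3, window = 0.5))
  reg <- abr_regressor(rep(list(x), n_ep), rep(list(x), n_ep), fs)
  resp_z <- deconvolve(z, reg, lags = c(0, 50))
  clean <- epochs_from_matrix(matrix(rep(y, n_ep), n_ep, byrow = TRUE), fs)
  resp_c <- deconvolve(clean, reg, lags = c(0, 50))
  # amplitude preserved within a few percent despite ~6% zeroed samples
  expect_equal(sd(resp_z$amplitude), sd(resp_c$amplitude), tolerance = 0.05)
})

test_that("averaging conditions with distinct regressor statistics helps", {
  fs <- 10000
  set.seed(21)
  kern <- abr_kernel(fs, max_lag_ms = 50)
  derive_one <- function(f0) {
    a <- make_speechlike_audio(8, f0_range = f0, pauses = FALSE)
    x <- (pmax(resample_waveform(pmax(a$samples, 0), a$fs, fs), 0) +
          pmax(resample_waveform(pmax(-a$samples, 0), a$fs, fs), 0)) / 2
    y <- speechABR:::conv_linear(x, kern$amplitude)[seq_along(x)] +
      rnorm(length(x), sd = 0.05)
    deconvolve(epochs_from_matrix(matrix(y, 1), fs),
               abr_regressor(list(x), list(x), fs), lags = c(-20, 50))
  }
  female <- derive_one(c(160, 250))   # differing fundamental ranges
  male <- derive_one(c(90, 140))
  avg <- combine_conditions(list(female, male))
  truth <- kernel_as_response(kern)
  r <- function(resp) correlate_window(resp, truth, window = c(0, 20))
  expect_gt(r(avg), max(r(female), r(male)))
})
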
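test_that("wave V picking finds known peaks with tie-break to earliest", {
  fs <- 10000
  lags <- seq(-10, 30, by = 0.1)   # ms grid at the 10-kHz sample spacing
  bump <- exp(-(lags - 6.5)^2 / (2 * 0.5^2))
  resp <- response_waveform(bump, lags, fs)
  wv <- find_wave_v(resp)
  expect_equal(wv$latency_ms, 6.5, tolerance = 0.1)
  expect_gt(wv$amplitude_uV, 0.9)

  # shift equivariance within the window
  resp_shift <- response_waveform(exp(-(lags - 5.8)^2 / (2 * 0.5^2)), lags, fs)
  expect_equal(find_wave_v(resp_shift)$latency_ms, 5.8, tolerance = 0.1)

  # exact tie at 5.5 and 6.5 ms -> earliest wins (no smoothing)
  flat <- numeric(length(lags))
  flat[lags == 5.5] <- 1; flat[lags == 6.5] <- 1
  tie <- response_waveform(flat, lags, fs)
  expect_equal(find_wave_v(tie, smooth_lp = NULL)$latency_ms, 5.5)

  expect_error(find_wave_v(response_waveform(1:5, 1:5 / 10, fs)), "window")
})

test_that("morphology correlation is scale and offset invariant", {
  fs <- 10000
  a <- kernel_as_response(abr_kernel(fs))
  expect_equal(correlate_window(a, a), 1.0)
  b <- a; b$amplitude <- -a$amplitude
  expect_equal(correlate_window(a, b), -1.0)
  c2 <- a; c2$amplitude <- 4.2 * a$amplitude + 17
  expect_equal(correlate_window(a, c2), 1.0)

  # null distribution at n = 201 samples: |r| < 0.25 nearly always
  set.seed(31)
  lags <- seq(0, 20, by = 0.1)
  rs <- replicate(40, {
    u <- response_waveform(rnorm(length(lags)), lags, fs)
    v <- response_waveform(rnorm(length(lags)), lags, fs)
    correlate_window(u, v)
  })
  expect_gte(mean(abs(rs) < 0.25), 0.95)
})

test_that("the SNR formula and its undefined region are respected", {
  fs <- 10000
  lags <- seq(-150, 350, by = 0.1)
  make_resp <- function(ratio) {
    set.seed(32)
    amp <- rnorm(length(lags))
    noise_i <- lags >= -125 & lags <= -10
    sig_i <- lags >= 0 & lags <= 20
    amp[noise_i] <- amp[noise_i] / sd(amp[noise_i])         # var 1
    amp[sig_i] <- amp[sig_i] / sd(amp[sig_i]) * sqrt(ratio) # var = ratio
    response_waveform(amp, lags, fs)
  }
  expect_equal(response_snr(make_resp(2))$snr_db, 0, tolerance = 1e-9)
  expect_equal(response_snr(make_resp(11))$snr_db, 10, tolerance = 1e-9)
  expect_true(is.na(response_snr(make_resp(0.5))$snr_db))
})

test_that("snr_curve grows with accumulating epochs", {
  fs <- 2000
  set.seed(33)
  x <- abs(rnorm(4 * fs))
  kern <- abr_kernel(fs, max_lag_ms = 50)
  sig <- speechABR:::conv_linear(x, kern$amplitude)[seq_along(x)]
  n_ep <- 16
  dat <- matrix(rep(sig, n_ep), n_ep, byrow = TRUE) +
    matrix(rnorm(n_ep * length(x), sd = 2), n_ep)
  ep <- epochs_from_matrix(dat, fs)
  reg <- abr_regressor(rep(list(x), n_ep), rep(list(x), n_ep), fs)
  sc <- snr_curve(ep, reg, at = c(4, 16), lp = 500)
  expect_false(anyNA(sc$snr_db))
  expect_gt(sc$snr_db[2], sc$snr_db[1])
  # two doublings: expect about +6 dB, generously bracketed
  expect_gt(sc$snr_db[2] - sc$snr_db[1], 2)
  expect_lt(sc$snr_db[2] - sc$snr_db[1], 10)
})

test_that("split-half correlations behave under drift and condition effects", {
  fs <- 2000
  set.seed(34)
  x <- abs(rnorm(4 * fs))
  kern <- abr_kernel(fs, max_lag_ms = 50)
  sig <- speechABR:::conv_linear(x, kern$amplitude)[seq_along(x)]
  n_ep <- 12
  reg <- abr_regressor(rep(list(x), n_ep), rep(list(x), n_ep), fs)

  # noiseless: both splits perfect
  clean <- epochs_from_matrix(matrix(rep(sig, n_ep), n_ep, byrow = TRUE), fs)
  expect_equal(split_half(clean, reg, lp = 500)$r, 1.0, tolerance = 1e-6)

  # slow drift: response shrinks over the session; the even/odd split
  # balances it across halves, the first/second split does not
  gain <- seq(1, 0.3, length.out = n_ep)
  drift <- epochs_from_matrix(
    t(sapply(gain, function(g) g * sig)) +
      matrix(rnorm(n_ep * length(x), sd = 0.5), n_ep), fs)
  r_oe <- split_half(drift, reg, lp = 500)$r
  r_fs <- split_half(drift, reg, split = "first_second", lp = 500)$r
  expect_gt(r_oe, r_fs)

  # narrator split: with a condition-specific kernel the narrator split
  # correlates lower than the balanced even/odd split
  kern2 <- abr_kernel(fs, latencies_ms = c(2, 4, 8, 30, 45),
                      max_lag_ms = 50)
  sig2 <- speechABR:::conv_linear(x, kern2$amplitude)[seq_along(x)]
  narrator <- rep(c(0, 1), n_ep / 2)
  dat <- t(sapply(seq_len(n_ep), function(k) {
    if (narrator[k] == 0) sig else sig2
  })) + matrix(rnorm(n_ep * length(x), sd = 0.5), n_ep)
  epn <- epochs_from_matrix(dat, fs)
  r_cond <- split_half(epn, reg, split = narrator, lp = 500)$r
  r_bal <- split_half(epn, reg, split = rep(c(0, 1), each = n_ep / 2), lp = 500)$r
  expect_gt(r_bal, r_cond)
})
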
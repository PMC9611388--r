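test_that("common-average reference zeroes the channel mean and is idempotent", {
  x <- matrix(c(5, -5, 12, 2), 2, 2, dimnames = list(c("a", "b"), NULL))
  y <- rereference_common_average(x)
  expect_equal(y[, 1], c(a = 5, b = -5))        # already zero-mean column
  expect_equal(colMeans(y), c(0, 0), tolerance = 1e-12, ignore_attr = TRUE)
  # constant offset on all channels vanishes
  z <- rereference_common_average(matrix(10, 3, 4,
                                         dimnames = list(letters[1:3], NULL)))
  expect_true(all(z == 0))
  # zero column means after the op, and idempotence
  r <- matrix(rnorm(50), 5, 10, dimnames = list(letters[1:5], NULL))
  rr <- rereference_common_average(r)
  expect_lt(max(abs(colMeans(rr))), 1e-12)
  expect_equal(rereference_common_average(rr), rr, tolerance = 1e-14)
  expect_error(rereference_common_average(matrix(1, 1, 10)), "2 channels")
})

test_that("zero-phase bandpass preserves passband tones and kills stopband", {
  fs <- 500
  t <- seq(1 / fs, 8, by = 1 / fs)
  x10 <- sin(2 * pi * 10 * t)
  y <- bandpass_zero_phase(x10, 1, 30, sampling_rate = fs)
  mid <- 1000:3000
  expect_lt(max(abs(y[mid] - x10[mid])), 0.01)  # amplitude and phase identity
  y50 <- bandpass_zero_phase(sin(2 * pi * 50 * t), 1, 30, sampling_rate = fs)
  expect_lt(max(abs(y50)), 0.01)
  ydc <- bandpass_zero_phase(rep(3, length(t)) + x10, 1, 30,
                             sampling_rate = fs)
  expect_lt(abs(mean(ydc)), 1e-6)
  expect_error(bandpass_zero_phase(x10, 1, 250, sampling_rate = fs),
               "Nyquist")
})

test_that("epoch extraction is event-locked with edge handling", {
  fs <- 500
  n <- fs * 20
  dat <- matrix(rnorm(2 * n), 2, n, dimnames = list(c("a", "b"), NULL))
  ev <- data.frame(sample = c(1L, 3000L, 6000L, n - 10L),
                   condition = c("A", "A", "B", "B"), session = "S1")
  rec <- eeg_recording(dat, fs, ev)
  ep <- extract_epochs(rec, -0.2, 1.0)
  expect_equal(dim(ep$data)[1], 2L)            # first and last dropped
  expect_equal(sum(!ep$rejection_log$kept), 2L)
  expect_match(ep$rejection_log$reason[1], "edge")
  expect_equal(dim(ep$data)[3], round(1.2 * fs) + 1L)
  expect_true(any(ep$times == 0))
  expect_equal(ep$conditions, c("A", "B"))
  # epoch content matches the raw slice
  expect_equal(ep$data[1, , ], dat[, (3000 - 100):(3000 + 500)],
               ignore_attr = TRUE)
})

test_that("amplitude rejection uses a strict threshold and logs decisions", {
  ep <- make_epochs(function(e) matrix(0, 2, 601), n_epochs = 3)
  ep$data[2, 1, 300] <- 101
  out <- reject_amplitude(ep, 100)
  expect_equal(dim(out$data)[1], 2L)
  expect_equal(sum(!out$rejection_log$kept), 1L)
  expect_match(out$rejection_log$reason[2], "amplitude")
  expect_equal(attr(out, "survival_fraction"), 2 / 3)
  # exactly at threshold is kept (strictly greater rejects)
  ep$data[2, 1, 300] <- 100
  expect_equal(dim(reject_amplitude(ep, 100)$data)[1], 3L)
  # all-zero epochs all kept
  expect_equal(dim(reject_amplitude(make_epochs(function(e)
    matrix(0, 2, 601)))$data)[1], 4L)
})

test_that("outlier-trial survival matches the generator's binomial rate", {
  frac <- 0.04
  cfg <- synth_config(montage = demo_m, sampling_rate = 125,
                      n_trials_per_condition = 125, conditions = c("A", "D"),
                      noise = list(alpha = 1, amplitude = 8),
                      blink_rate = 0, outlier_trial_fraction = frac,
                      seed = 77)
  ep <- extract_epochs(generate_recording(cfg))
  out <- reject_amplitude(ep, 100)
  n <- dim(ep$data)[1]
  dropped <- n - dim(out$data)[1]
  bounds <- stats::qbinom(c(0.005, 0.995), n, frac)
  expect_gte(dropped, bounds[1])
  expect_lte(dropped, bounds[2])
})

test_that("band splitting routes tones to their own band only", {
  fs <- 500
  mk <- function(f) make_epochs(function(e) {
    rbind(sin(2 * pi * f * seq(-0.2, 1.0, by = 1 / fs)),
          cos(2 * pi * f * seq(-0.2, 1.0, by = 1 / fs)))
  }, n_epochs = 2)
  bands <- filter_bands(mk(10))
  expect_named(bands, c("delta", "theta", "alpha", "beta"))
  expect_true(all(vapply(bands, function(b) dim(b$data)[1], numeric(1)) == 2))
  mid <- 150:450
  # short-epoch spectral leakage bounds out-of-band residuals near -20 dB
  amp <- vapply(bands, function(b) max(abs(b$data[1, 1, mid])), numeric(1))
  expect_gt(amp["alpha"], 0.9)
  expect_true(all(amp[c("delta", "theta", "beta")] < 0.1))
  amp20 <- vapply(filter_bands(mk(20)), function(b)
    max(abs(b$data[1, 1, mid])), numeric(1))
  expect_gt(amp20["beta"], 0.9)
  expect_true(all(amp20[c("delta", "theta", "alpha")] < 0.1))
})

test_that("per-epoch filtering approximates continuous filtering away from edges", {
  # narrowband kernels are longer than an epoch, so the mirror-padded
  # per-epoch filter can only approximate filtering the continuous record;
  # mid-epoch the two paths must agree closely in waveform
  cfg <- quick_cfg(n_trials_per_condition = 4, seed = 60)
  rec <- generate_recording(cfg)
  for (band in list(c(1, 30), c(8, 13))) {
    ef <- bandpass_zero_phase(extract_epochs(rec), band[1], band[2])
    fe <- extract_epochs(bandpass_zero_phase(rec, band[1], band[2]))
    mid <- abs(ef$times - 0.4) <= 0.3
    r <- stats::cor(as.vector(ef$data[, , mid]), as.vector(fe$data[, , mid]))
    expect_gt(r, 0.97)
  }
})
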
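test_that("Morlet transform has a flat, linear, resolved ridge structure", {
  fs <- 500
  t <- seq(-0.2, 1.0, by = 1 / fs)
  x <- matrix(2 * cos(2 * pi * 10 * t), 1, dimnames = list("ch", NULL))
  m <- morlet_tfr(x, fs, freqs = c(6, 10, 20))
  mid <- 150:450
  ridge <- m[1, 2, mid]
  expect_equal(mean(ridge), 2, tolerance = 0.02)
  expect_lt(stats::sd(ridge) / mean(ridge), 0.05)
  expect_gt(mean(m[1, 2, mid]), 5 * mean(m[1, 1, mid]))
  # linearity: doubling the amplitude doubles the ridge
  m2 <- morlet_tfr(2 * x, fs, freqs = c(6, 10, 20))
  expect_equal(m2[1, 2, mid], 2 * m[1, 2, mid], tolerance = 1e-9)
  # two tones resolved with n_cycles = 5
  x2 <- matrix(sin(2 * pi * 6 * t) + sin(2 * pi * 20 * t), 1,
               dimnames = list("ch", NULL))
  fr <- seq(4, 24, by = 2)
  mm <- apply(morlet_tfr(x2, fs, fr, n_cycles = 5)[1, , mid], 1L, mean)
  pk <- fr[eegplv:::find_peaks(mm, prominence = 0.2)]
  expect_setequal(pk, c(6, 20))
  expect_error(morlet_tfr(x, fs, freqs = c(10, 400)), "Nyquist")
})

test_that("ERSP of a stationary tone is 0 dB and gains map to dB exactly", {
  fs <- 500
  ep <- make_epochs(function(e) {
    t <- seq(-0.2, 1.0, by = 1 / fs)
    rbind(10 * cos(2 * pi * 10 * t + e), 10 * sin(2 * pi * 10 * t + e))
  }, n_epochs = 3)
  e <- ersp(ep, freqs = c(8, 10, 12))
  # residual wavelet edge decay leaks <0.2 dB into the short baseline
  expect_lt(max(abs(e$values[, 2, 100:500])), 0.2)
  # amplitude modulation by known gain
  ep2 <- make_epochs(function(e) {
    t <- seq(-0.2, 1.0, by = 1 / fs)
    g <- ifelse(t >= 0.4 & t <= 0.8, 0.5, 1)
    rbind(10 * g * cos(2 * pi * 10 * t + e),
          10 * g * sin(2 * pi * 10 * t + e))
  }, n_epochs = 3)
  e2 <- ersp(ep2, freqs = 10)
  w <- ep2$times >= 0.5 & ep2$times <= 0.7
  expect_equal(mean(e2$values[, 1, w]), 10 * log10(0.5), tolerance = 0.3)
  # power convention doubles the dB scale
  e2p <- ersp(ep2, freqs = 10, convention = "power")
  expect_equal(mean(e2p$values[, 1, w]), 20 * log10(0.5), tolerance = 0.6)
})

test_that("synthetic ERD/ERS gains are recovered within 1 dB", {
  cfg <- quick_cfg(
    n_trials_per_condition = 8, conditions = "A", seed = 62,
    power_specs = list(
      power_mod_spec("CP3", c(8, 13), gain = 0.5, window = c(0.35, 0.75)),
      power_mod_spec("C4", c(8, 13), gain = 2.0, window = c(0.35, 0.75))))
  ep <- extract_epochs(bandpass_zero_phase(generate_recording(cfg)))
  e <- ersp(ep, freqs = c(8, 10.5, 13), channels = c("CP3", "C4"))
  w <- e$times >= 0.45 & e$times <= 0.65
  erd <- mean(e$values["CP3", , w])
  ers <- mean(e$values["C4", , w])
  expect_equal(erd, 10 * log10(0.5), tolerance = 1)
  expect_equal(ers, 10 * log10(2.0), tolerance = 1)
})

test_that("ERSP baseline normalization holds on the baseline window", {
  fs <- 500
  # deterministic stationary input: exactly 0 dB after baseline averaging
  ep <- make_epochs(function(e) {
    t <- seq(-0.2, 1.0, by = 1 / fs)
    rbind(5 * cos(2 * pi * 11 * t + e), 5 * sin(2 * pi * 9 * t + e))
  }, n_epochs = 4)
  e <- ersp(ep, freqs = c(9, 11))
  # average over the part of the baseline clear of the wavelet edge zone
  bsel <- e$times >= -0.1 & e$times <= 0
  expect_lt(max(abs(apply(e$values[, , bsel], 1:2, mean))), 0.2)
  # stochastic input: small negative log-magnitude bias, bounded by ~1 dB
  set.seed(9)
  epn <- make_epochs(function(e) {
    matrix(rnorm(2 * 601), 2, 601)
  }, n_epochs = 40)
  en <- ersp(epn, freqs = c(10, 20))
  expect_lt(max(abs(apply(en$values[, , bsel], 1:2, mean))), 1)
})

test_that("surface Laplacian has the finite-difference operator signature", {
  m <- full_m
  u <- stats::setNames(rep(3, nrow(m)), m$channel)
  expect_true(all(abs(surface_laplacian(u, m)) < 1e-12))
  # single-channel hotspot: positive centre, negative neighbours, ~0 far away
  h <- stats::setNames(rep(0, nrow(m)), m$channel)
  h["Cz"] <- 1
  lh <- surface_laplacian(h, m)
  expect_equal(unname(lh["Cz"]), 1, tolerance = 1e-12)
  nb <- c("C1", "C2", "FCz", "CPz")
  expect_true(all(lh[nb] < 0))
  expect_true(all(abs(lh[c("O1", "Fp2", "T7")]) < 1e-12))
  # approximate annihilation of a linear gradient over the cap interior
  g <- stats::setNames(m$y, m$channel)
  lg <- surface_laplacian(g, m)
  interior <- !(m$channel %in% c("Fp1", "Fpz", "Fp2", "O1", "Oz", "O2",
                                 "Iz", "P9", "P10", "T7", "T8", "AF7", "AF8",
                                 "F7", "F8", "FT7", "FT8", "TP7", "TP8",
                                 "P7", "P8", "PO7", "PO8"))
  expect_lt(max(abs(lg[interior])), 0.1 * diff(range(g)))
  expect_error(surface_laplacian(c(X99 = 1), m), "X99")
})

test_that("mu-rhythm ERD timing is recovered from generator truth", {
  cfg <- quick_cfg(
    n_trials_per_condition = 8, conditions = "A", seed = 71,
    power_specs = list(
      power_mod_spec("CP3", c(8, 13), gain = 0.5, window = c(0.35, 0.45))))
  ep <- extract_epochs(bandpass_zero_phase(generate_recording(cfg)))
  e <- ersp(ep, freqs = c(8, 10.5, 13), channels = "CP3")
  mu <- mu_erd_ers(e, "CP3")
  expect_lt(abs(mu$erd$time - 0.40), 0.05)
  expect_lt(mu$erd$value, -1)
  expect_error(mu_erd_ers(e, c("CP3", "C5")), "C5")
  # no modulation: ROI-averaged time course stays within 1 dB
  cfg0 <- quick_cfg(n_trials_per_condition = 48, conditions = "A", seed = 72)
  ep0 <- extract_epochs(bandpass_zero_phase(generate_recording(cfg0)))
  e0 <- ersp(ep0, freqs = c(8, 10.5, 13), channels = c("C3", "CP3", "CP4"))
  mu0 <- mu_erd_ers(e0, c("C3", "CP3", "CP4"))
  expect_lt(max(abs(mu0$timecourse[mu0$valid & e0$times > -0.1])), 1)
})

test_that("ERP lateralization captures asymmetry, peaks and condition contrast", {
  mk <- function(erps, seed) quick_cfg(
    n_trials_per_condition = 24, seed = seed,
    noise = list(alpha = 1, amplitude = 2), erp_specs = erps)
  # symmetric component: difference stays near the noise floor
  cfg_s <- mk(list(erp_spec(c("PO7", "PO8"), 0.25,
                            amplitude = c(PO7 = 6, PO8 = 6))), 81)
  ep_s <- extract_epochs(bandpass_zero_phase(generate_recording(cfg_s)))
  lat_s <- erp_lateralization(ep_s)
  expect_lt(max(abs(lat_s$window_stats$mean)), 1.0)
  # right-dominant component: negative left-minus-right deflection
  cfg_a <- mk(list(erp_spec(c("PO7", "PO8"), 0.25,
                            amplitude = c(PO7 = 3, PO8 = 6))), 82)
  ep_a <- extract_epochs(bandpass_zero_phase(generate_recording(cfg_a)))
  lat_a <- erp_lateralization(ep_a, window = c(0.20, 0.30))
  expect_lt(min(lat_a$window_stats$mean), -1.5)
  # two asymmetric components: two lateralization peaks
  cfg_2 <- mk(list(
    erp_spec(c("PO7", "PO8"), 0.15, amplitude = c(PO7 = 2, PO8 = 6)),
    erp_spec(c("PO7", "PO8"), 0.30, amplitude = c(PO7 = 6, PO8 = 2))), 83)
  ep_2 <- extract_epochs(bandpass_zero_phase(generate_recording(cfg_2)))
  lat_2 <- erp_lateralization(ep_2, prominence = 1)
  pk <- lat_2$peaks[["A"]]
  expect_gte(length(pk), 2L)
  expect_true(any(abs(pk - 0.15) < 0.05) && any(abs(pk - 0.30) < 0.05))
  expect_error(erp_lateralization(ep_2, conditions = "Z"), "Z")
  expect_error(erp_lateralization(ep_2, left = "Nope"), "Nope")
})
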
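test_that("identical configurations yield bit-identical recordings", {
  cfg <- quick_cfg(n_trials_per_condition = 3, seed = 9)
  r1 <- generate_recording(cfg)
  r2 <- generate_recording(cfg)
  expect_identical(r1$data, r2$data)
  expect_identical(r1$events, r2$events)
  r3 <- generate_recording(quick_cfg(n_trials_per_condition = 3, seed = 10))
  expect_false(identical(r1$data, r3$data))
})

test_that("configuration invariants are enforced", {
  expect_error(quick_cfg(outlier_trial_fraction = 1.5), "outlier")
  expect_error(quick_cfg(channel_names = c("Oz", "NotThere")), "NotThere")
  # coupling window must sit inside the epoch window
  expect_error(
    quick_cfg(coupling_specs = list(
      coupling_spec("C3", 5, window = c(0.9, 1.4)))),
    "epoch window")
  # sampling rate must clear twice the highest synthesized frequency
  expect_error(quick_cfg(sampling_rate = 50), "sampling_rate")
})

test_that("without artifacts no epoch exceeds the 100 uV rejection bound", {
  cfg <- quick_cfg(n_trials_per_condition = 4,
                   noise = list(alpha = 1, amplitude = 15), seed = 21)
  rec <- generate_recording(cfg)
  ep <- extract_epochs(rec)
  expect_lt(max(abs(ep$data)), 100)
})

test_that("coupling injects a spectral peak at the band centre", {
  # ~65 s recording with sustained 6 Hz occipital-seeded coupling
  cfg <- quick_cfg(n_trials_per_condition = 10, seed = 33,
                   coupling_specs = list(
                     coupling_spec("C3", band_center = 6, concentration = 4,
                                   window = c(0.05, 0.95), amplitude = 20)))
  rec <- generate_recording(cfg)
  expect_gt(ncol(rec$data) / rec$sampling_rate, 60)
  sp <- stats::spec.pgram(stats::ts(rec$data["C3", ], frequency = 500),
                          spans = 31, plot = FALSE, taper = 0.1)
  sel <- sp$freq >= 2 & sp$freq <= 20
  peak_f <- sp$freq[sel][which.max(sp$spec[sel])]
  expect_lt(abs(peak_f - 6), 1)
})

test_that("target-seed phase concentration increases monotonically with kappa", {
  conc <- vapply(c(1, 2, 4, 8), function(k) {
    cfg <- quick_cfg(n_trials_per_condition = 20, conditions = "A", seed = 40,
                     coupling_specs = list(
                       coupling_spec("C3", band_center = 6, concentration = k,
                                     window = c(0.1, 0.6), amplitude = 40)))
    ep <- extract_epochs(bandpass_zero_phase(generate_recording(cfg), 4, 8))
    seed_ph <- instantaneous_phase(fuse_occipital(ep, demo_m), 500)
    tgt_ph <- instantaneous_phase(ep$data[, match("C3", ep$channels), ], 500)
    mid <- which.min(abs(ep$times - 0.35))
    d <- seed_ph[, mid] - tgt_ph[, mid]
    sqrt(mean(cos(d))^2 + mean(sin(d))^2)   # circular resultant length
  }, numeric(1))
  expect_true(all(diff(conc) > 0))
})

test_that("infinite concentration and zero lag give identical in-window phases", {
  cfg <- quick_cfg(n_trials_per_condition = 4, conditions = "A", seed = 55,
                   noise = list(alpha = 1, amplitude = 0.01),
                   coupling_specs = list(
                     coupling_spec("C3", band_center = 6, phase_lag = 0,
                                   concentration = Inf, window = c(0.1, 0.6),
                                   amplitude = 50)))
  ep <- extract_epochs(bandpass_zero_phase(generate_recording(cfg), 4, 8))
  seed_ph <- instantaneous_phase(fuse_occipital(ep, demo_m), 500)
  tgt_ph <- instantaneous_phase(ep$data[, match("C3", ep$channels), ], 500)
  win <- ep$times >= 0.15 & ep$times <= 0.55
  d <- abs(eegplv:::wrap_angle(seed_ph[, win] - tgt_ph[, win]))
  expect_lt(stats::median(d), 0.05)
})

test_that("ground-truth tables mirror the configured effects", {
  cfg <- quick_cfg(
    coupling_specs = list(coupling_spec("C3", 5.5, conditions = "A")),
    power_specs = list(power_mod_spec(c("CP3", "CP4"), gain = 0.5,
                                      conditions = c("A", "D"))),
    erp_specs = list(erp_spec(c("PO7", "PO8"), 0.25,
                              amplitude = c(PO7 = 2, PO8 = 4))))
  gt <- ground_truth(cfg)
  expect_equal(nrow(gt$coupling), 1L)
  expect_equal(gt$coupling$channel, "C3")
  expect_equal(nrow(gt$power), 4L)     # 2 channels x 2 conditions
  expect_equal(nrow(gt$erp), 4L)       # 2 channels x 2 configured conditions
  expect_equal(gt$erp$amplitude[gt$erp$channel == "PO8"], c(4, 4))
  # referential integrity
  all_ch <- c(gt$coupling$channel, gt$power$channel, gt$erp$channel)
  expect_true(all(all_ch %in% cfg$channel_names))
  # empty spec lists give empty tables
  gt0 <- ground_truth(quick_cfg())
  expect_equal(nrow(gt0$coupling), 0L)
  expect_equal(nrow(gt0$power), 0L)
  expect_equal(nrow(gt0$erp), 0L)
})
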
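test_that("occipital fusion is the arithmetic mean of the seed channels", {
  ep <- make_epochs(function(e) matrix(e, 6, 601),
                    channels = c("Oz", "O1", "O2", "POz", "PO3", "PO4"),
                    n_epochs = 3)
  f <- fuse_occipital(ep, demo_m)
  expect_equal(f, matrix(rep(1:3, 601), 3, 601))   # identical channels
  # linearity: fuse(a + b) = fuse(a) + fuse(b)
  epa <- make_epochs(function(e) matrix(rnorm(6 * 601), 6, 601),
                     channels = c("Oz", "O1", "O2", "POz", "PO3", "PO4"),
                     n_epochs = 2)
  epb <- epa; epb$data <- array(rnorm(length(epa$data)), dim(epa$data),
                                dimnames = dimnames(epa$data))
  eps <- epa; eps$data <- epa$data + epb$data
  expect_equal(fuse_occipital(eps, demo_m),
               fuse_occipital(epa, demo_m) + fuse_occipital(epb, demo_m),
               tolerance = 1e-12)
  ep_bad <- make_epochs(function(e) matrix(0, 2, 601),
                        channels = c("Oz", "O1"))
  expect_error(fuse_occipital(ep_bad, demo_m), "POz")
})

test_that("instantaneous phase follows the analytic-signal identities", {
  fs <- 500
  t <- seq(1 / fs, 4, by = 1 / fs)
  ph <- instantaneous_phase(cos(2 * pi * 10 * t), fs)
  mid <- 300:1700
  slope <- diff(ph)[mid]; slope <- slope[abs(slope) < pi]
  expect_equal(mean(slope) * fs / (2 * pi), 10, tolerance = 0.01)
  # wrap count: a 10 Hz tone wraps 10 times per second
  wraps <- sum(diff(ph[1000:1500]) < -pi)
  expect_equal(wraps, 10)
  # sin lags cos by pi/2
  ps <- instantaneous_phase(sin(2 * pi * 10 * t), fs)
  d <- eegplv:::wrap_angle(ph[mid] - ps[mid])
  expect_equal(mean(d), pi / 2, tolerance = 0.01)
  expect_error(instantaneous_phase(rep(1, 100), fs), "constant")
})

test_that("PLV is exact for locked phases and bounded/symmetric in general", {
  p1 <- matrix(runif(50 * 40, -pi, pi), 50, 40)
  expect_true(all(abs(plv_series(p1, p1)$values - 1) < 1e-12))
  p2 <- matrix(runif(50 * 40, -pi, pi), 50, 40)
  v12 <- plv_series(p1, p2)$values
  expect_true(all(v12 >= 0 & v12 <= 1))
  expect_equal(v12, plv_series(p2, p1)$values, tolerance = 1e-12)
  # sqrt convention is the square root of the printed (squared) form
  expect_equal(plv_series(p1, p2, convention = "sqrt")$values, sqrt(v12),
               tolerance = 1e-12)
  expect_error(plv_series(p1[1, , drop = FALSE], p2[1, , drop = FALSE]),
               "2 epochs")
  expect_error(plv_series(p1, p2[, 1:10]), "identical dimensions")
})

test_that("PLV recovers the squared Bessel-ratio mean resultant for von Mises jitter", {
  set.seed(31)
  # kappa = 2, n = 200: (I1/I0)^2 ~ 0.487
  d <- matrix(eegplv:::rvonmises(200 * 60, 0.7, 2), 200, 60)
  v <- plv_series(d, matrix(0, 200, 60))$values
  expect_equal(mean(v), eegplv:::vm_resultant(2)^2, tolerance = 0.05)
  # uniform phases: E[PLV] = 1/n
  u <- matrix(runif(100 * 200, -pi, pi), 100, 200)
  vn <- plv_series(u, matrix(0, 100, 200))$values
  expect_equal(mean(vn) * 100, 1, tolerance = 0.3)
})

test_that("bootstrap baseline mean is exact, convex and consistent", {
  v <- c(rep(0.3, 50))
  expect_equal(bootstrap_baseline_mean(v, n_boot = 200, seed = 1), 0.3)
  set.seed(5)
  x <- runif(30)
  g <- bootstrap_baseline_mean(x, n_boot = 500, seed = 2)
  expect_gte(g, min(x)); expect_lte(g, max(x))
  # law of large numbers on a two-point baseline
  g2 <- bootstrap_baseline_mean(rep(c(0.1, 0.5), 25), n_boot = 10000,
                                seed = 3)
  expect_equal(g2, 0.3, tolerance = 0.01)
  expect_error(bootstrap_baseline_mean(0.5, n_boot = 10), "at least 2")
})

test_that("ePLV screen is silent on null input and respects alpha", {
  nt <- 61
  times <- seq(-0.2, 1.0, length.out = nt)
  # constant series equal their own baseline: no cell can be flagged
  const <- matrix(0.25, 4, nt, dimnames = list(paste0("e", 1:4), NULL))
  m <- screen_eplv(list(const, const, const), times = times, n_boot = 300,
                   seed = 4)
  expect_false(any(m$significant))
  # alpha = 0 flags nothing even with real effects
  set.seed(8)
  plvs <- lapply(1:4, function(i) {
    x <- matrix(runif(4 * nt, 0, 0.1), 4, nt,
                dimnames = list(paste0("e", 1:4), NULL))
    x[1, times > 0.2] <- x[1, times > 0.2] + 0.5
    x
  })
  m0 <- screen_eplv(plvs, times = times, alpha = 0, n_boot = 300, seed = 4)
  expect_false(any(m0$significant))
  # with alpha = 0.05 the injected electrode is detected
  m1 <- screen_eplv(plvs, times = times, n_boot = 500, seed = 4)
  expect_gt(mean(m1$significant["e1", m1$times > 0.25]), 0.9)
  expect_error(screen_eplv(plvs[1], times = times), "2 participants")
})

test_that("null screen flag rate stays near the nominal level", {
  set.seed(77)
  nt <- 40
  times <- seq(-0.2, 1.0, length.out = nt)
  # PLV series of genuinely uncoupled phases, 6 participants x 5 electrodes
  plvs <- lapply(1:6, function(i) {
    m <- t(vapply(1:5, function(ch) {
      plv_series(matrix(runif(60 * nt, -pi, pi), 60, nt),
                 matrix(runif(60 * nt, -pi, pi), 60, nt))$values
    }, numeric(nt)))
    rownames(m) <- paste0("e", 1:5)
    m
  })
  m <- screen_eplv(plvs, times = times, n_boot = 400, seed = 11)
  post <- m$times > 0
  expect_lt(mean(m$significant[, post]), 0.12)
})

test_that("connection summary counts cells and breaks peak ties earliest", {
  nt <- 20
  times <- seq(-0.2, 0.75, length.out = nt)
  sig <- matrix(FALSE, 3, nt, dimnames = list(paste0("e", 1:3), NULL))
  mk <- function(s) structure(list(significant = s, p = 1 - s,
                                   times = times, alpha = 0.05),
                              class = "eplv_mask")
  cs0 <- connection_summary(mk(sig))
  expect_true(all(cs0$counts$n_connections == 0))
  expect_equal(cs0$peak_time, times[1])     # earliest on an all-tie
  sig1 <- sig; sig1[2, 9] <- TRUE
  cs1 <- connection_summary(mk(sig1))
  expect_equal(cs1$peak_time, times[9])
  expect_equal(cs1$peak_count, 1)
  sig2 <- sig; sig2[, 5] <- TRUE; sig2[1:2, 12] <- TRUE; sig2[3, 15] <- TRUE
  cs2 <- connection_summary(mk(sig2))
  expect_equal(sum(cs2$counts$n_connections), sum(sig2))
  expect_equal(cs2$peak_time, times[5])
})
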
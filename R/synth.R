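#' Synthetic event-related EEG with known ground truth
#'
#' `synth_config()` assembles and validates the generator configuration;
#' [generate_recording()] realizes it as a continuous multichannel
#' recording with event markers; [ground_truth()] returns machine-readable
#' tables of every injected effect, for scoring detection performance.
#'
#' The generator emulates the statistical structure of a visual
#' object-presentation experiment: four stimulus conditions (A-D), a fixed
#' number of trials per condition per session, 1 s fixation before each
#' stimulus and a 1-2 s jittered inter-trial interval, pink-noise (1/f)
#' background, narrowband phase coupling from an occipital seed region to
#' distal electrodes with von-Mises phase jitter, multiplicative band-power
#' modulation (ERD/ERS), Gaussian-windowed ERP deflections, frontal-dominant
#' blink transients and occasional high-amplitude outlier trials.
#'
#' @param sampling_rate sampling rate in Hz (default 500).
#' @param montage an [eeg_montage][generate_montage]; channel names are
#'   taken from it unless `channel_names` is given.
#' @param channel_names subset of montage channels to synthesize.
#' @param n_trials_per_condition trials per condition (default 35, i.e.
#'   140 trials per session over four conditions).
#' @param conditions condition labels (default `c("A","B","C","D")`).
#' @param session session label attached to every event.
#' @param epoch_window c(start, end) of the analysis epoch in seconds
#'   relative to stimulus onset (default `c(-0.2, 1.0)`).
#' @param noise list with `alpha` (spectral exponent of the 1/f^alpha
#'   background, default 1) and `amplitude` (per-channel standard deviation
#'   in microvolts, default 10).
#' @param coupling_specs list of [coupling_spec()] objects.
#' @param power_specs list of [power_mod_spec()] objects.
#' @param erp_specs list of [erp_spec()] objects.
#' @param blink_rate blink events per minute (default 10).
#' @param blink_amplitude blink peak amplitude at the frontal pole, uV.
#' @param outlier_trial_fraction fraction of trials carrying a >100 uV
#'   excursion (default 0.02).
#' @param stimulus_duration stimulus presentation time in seconds.
#' @param seed integer seed; identical configurations produce bit-identical
#'   recordings.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(sampling_rate = 500,
                         montage = generate_montage("paper64"),
                         channel_names = NULL,
                         n_trials_per_condition = 35,
                         conditions = c("A", "B", "C", "D"),
                         session = "S1",
                         epoch_window = c(-0.2, 1.0),
                         noise = list(alpha = 1, amplitude = 10),
                         coupling_specs = list(),
                         power_specs = list(),
                         erp_specs = list(),
                         blink_rate = 10,
                         blink_amplitude = 200,
                         outlier_trial_fraction = 0.02,
                         stimulus_duration = 1.0,
                         seed = 1L) {
  stopifnot(inherits(montage, "eeg_montage"))
  channel_names <- channel_names %||% montage$channel
  missing <- setdiff(channel_names, montage$channel)
  if (length(missing)) {
    stop("channel_names not in montage: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!(outlier_trial_fraction >= 0 && outlier_trial_fraction <= 1)) {
    stop("outlier_trial_fraction must be in [0, 1]", call. = FALSE)
  }
  stopifnot(length(epoch_window) == 2L, epoch_window[1] < epoch_window[2],
            blink_rate >= 0, n_trials_per_condition >= 1,
            noise$amplitude >= 0, noise$alpha >= 0)
  cfg <- structure(list(
    sampling_rate = sampling_rate, montage = montage,
    channel_names = channel_names,
    n_trials_per_condition = as.integer(n_trials_per_condition),
    conditions = conditions, session = session,
    epoch_window = epoch_window, noise = noise,
    coupling_specs = coupling_specs, power_specs = power_specs,
    erp_specs = erp_specs,
    blink_rate = blink_rate, blink_amplitude = blink_amplitude,
    outlier_trial_fraction = outlier_trial_fraction,
    stimulus_duration = stimulus_duration,
    seed = as.integer(seed)), class = "synth_config")
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  regions <- montage_regions(cfg$montage)
  top_freq <- 30
  for (cs in cfg$coupling_specs) {
    stopifnot(inherits(cs, "coupling_spec"))
    top_freq <- max(top_freq, cs$band_center)
    if (!(cs$seed_region %in% names(regions))) {
      stop("coupling seed_region ", cs$seed_region, " is not a montage region",
           call. = FALSE)
    }
    bad <- setdiff(cs$target_channels, cfg$channel_names)
    if (length(bad)) {
      stop("coupling target channels not synthesized: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    if (cs$window[1] < cfg$epoch_window[1] || cs$window[2] > cfg$epoch_window[2]) {
      stop("coupling window [", cs$window[1], ", ", cs$window[2],
           "] s lies outside the epoch window", call. = FALSE)
    }
  }
  for (ps in cfg$power_specs) {
    stopifnot(inherits(ps, "power_mod_spec"))
    top_freq <- max(top_freq, ps$band[2])
    bad <- setdiff(ps$channels, cfg$channel_names)
    if (length(bad)) {
      stop("power-modulation channels not synthesized: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  for (es in cfg$erp_specs) {
    stopifnot(inherits(es, "erp_spec"))
    bad <- setdiff(es$channels, cfg$channel_names)
    if (length(bad)) {
      stop("ERP channels not synthesized: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    if (es$latency < cfg$epoch_window[1] || es$latency > cfg$epoch_window[2]) {
      stop("ERP latency outside the epoch window", call. = FALSE)
    }
  }
  if (cfg$sampling_rate <= 2 * top_freq) {
    stop("sampling_rate must exceed twice the highest synthesized frequency (",
         top_freq, " Hz)", call. = FALSE)
  }
  invisible(cfg)
}

#' Ground-truth phase-coupling specification
#'
#' Adds a band-limited oscillation to every channel of `seed_region` and a
#' phase-shifted copy, jittered per trial by a von Mises(0, `concentration`)
#' angle, to each target channel, inside `window` (25 ms cosine ramps sit
#' outside the window so the full effect covers it).
#'
#' @param target_channels channels receiving the coupled copy.
#' @param band_center oscillation frequency, Hz.
#' @param seed_region montage region whose channels carry the source
#'   oscillation (default `"OCC_SEED"`).
#' @param phase_lag systematic seed-to-target phase lag, radians.
#' @param concentration von Mises kappa of the per-trial phase jitter;
#'   `Inf` means no jitter.
#' @param window c(start, end) seconds post-onset.
#' @param conditions conditions in which the coupling is present.
#' @param amplitude oscillation amplitude, uV.
#' @export
coupling_spec <- function(target_channels, band_center,
                          seed_region = "OCC_SEED", phase_lag = 0,
                          concentration = 4, window = c(0.15, 0.40),
                          conditions = c("A", "B", "C", "D"),
                          amplitude = 15) {
  stopifnot(concentration >= 0, length(window) == 2L, window[1] < window[2],
            band_center > 0, amplitude > 0)
  structure(list(seed_region = seed_region,
                 target_channels = target_channels,
                 band_center = band_center, phase_lag = phase_lag,
                 concentration = concentration, window = window,
                 conditions = conditions, amplitude = amplitude),
            class = "coupling_spec")
}

#' Ground-truth band-power modulation (ERD/ERS)
#'
#' A narrowband oscillation at the band centre runs through the whole epoch
#' span; inside `window` its envelope is multiplied by `gain` (gain < 1
#' emulates event-related desynchronization, gain > 1 synchronization).
#'
#' @param channels channels carrying the oscillation.
#' @param band c(low, high) Hz; the oscillation sits at the band centre.
#' @param gain envelope multiplier inside `window` (> 0).
#' @param window c(start, end) seconds post-onset.
#' @param conditions conditions in which the modulation is present.
#' @param amplitude baseline oscillation amplitude, uV.
#' @export
power_mod_spec <- function(channels, band = c(8, 13), gain,
                           window = c(0.3, 0.6),
                           conditions = c("A", "B", "C", "D"),
                           amplitude = 20) {
  stopifnot(gain > 0, length(band) == 2L, band[1] < band[2],
            length(window) == 2L, window[1] < window[2], amplitude > 0)
  structure(list(channels = channels, band = band, gain = gain,
                 window = window, conditions = conditions,
                 amplitude = amplitude), class = "power_mod_spec")
}

#' Ground-truth event-related potential
#'
#' A Gaussian-windowed deflection added identically on every trial of the
#' selected conditions.  `amplitude` may be a named vector (one entry per
#' channel) to create lateral asymmetries.
#'
#' @param channels channels receiving the deflection.
#' @param latency peak time, seconds post-onset.
#' @param width Gaussian standard deviation, seconds.
#' @param amplitude peak amplitude in uV; scalar or named per-channel.
#' @param conditions conditions in which the component appears.
#' @export
erp_spec <- function(channels, latency, width = 0.03, amplitude = 5,
                     conditions = c("A", "B", "C", "D")) {
  if (length(amplitude) > 1L) {
    stopifnot(!is.null(names(amplitude)), all(channels %in% names(amplitude)))
  }
  stopifnot(width > 0)
  structure(list(channels = channels, latency = latency, width = width,
                 amplitude = amplitude, conditions = conditions),
            class = "erp_spec")
}

#' Continuous multichannel recording container
#'
#' @param data channels x samples matrix of potentials in microvolts, with
#'   rownames giving channel labels.
#' @param sampling_rate Hz.
#' @param events data frame with columns `sample` (1-based onset index),
#'   `condition`, `session`.
#' @return object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, sampling_rate, events) {
  stopifnot(is.matrix(data), !is.null(rownames(data)),
            is.data.frame(events),
            all(c("sample", "condition", "session") %in% names(events)))
  if (nrow(events) && (any(events$sample < 1) || any(events$sample > ncol(data)))) {
    stop("event sample indices must lie within the recording", call. = FALSE)
  }
  structure(list(data = data, sampling_rate = sampling_rate,
                 channels = rownames(data), events = events),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("<eeg_recording> ", nrow(x$data), " channels x ", ncol(x$data),
      " samples @ ", x$sampling_rate, " Hz (",
      round(ncol(x$data) / x$sampling_rate, 1), " s), ",
      nrow(x$events), " events\n", sep = "")
  invisible(x)
}

# Envelope that is `1` inside [w0, w1] with cosine ramps of `ramp` seconds
# *outside* the window; t is a vector of times.
window_envelope <- function(t, w0, w1, ramp = 0.025) {
  e <- numeric(length(t))
  e[t >= w0 & t <= w1] <- 1
  up <- t >= (w0 - ramp) & t < w0
  e[up] <- 0.5 * (1 - cos(pi * (t[up] - (w0 - ramp)) / ramp))
  dn <- t > w1 & t <= (w1 + ramp)
  e[dn] <- 0.5 * (1 + cos(pi * (t[dn] - w1) / ramp))
  e
}

# Pink (1/f^alpha) noise, one channel, unit variance before scaling.
pink_noise <- function(n, srate, alpha) {
  n2 <- stats::nextn(n, c(2, 3, 5))  # keep the FFT on a smooth length
  w <- stats::rnorm(n2)
  if (alpha == 0) return(w[seq_len(n)])
  X <- stats::fft(w)
  f <- seq(0, srate, length.out = n2 + 1L)[seq_len(n2)]
  f <- pmin(f, srate - f)            # two-sided frequency magnitude
  sc <- 1 / pmax(f, 0.5)^(alpha / 2) # flatten below 0.5 Hz
  sc[1L] <- 0                        # remove DC
  x <- Re(stats::fft(X * sc, inverse = TRUE))[seq_len(n)] / n2
  x / stats::sd(x)
}

#' Generate a continuous synthetic recording
#'
#' Realizes a [synth_config()]: trial schedule (1 s fixation, stimulus,
#' jittered 1-2 s inter-trial interval), pink-noise background, and all
#' configured coupling / power-modulation / ERP / blink / outlier effects.
#' Fully reproducible from the configuration seed.
#'
#' @param config a `synth_config`.
#' @return an [eeg_recording] with a `truth` attribute holding the
#'   [ground_truth()] tables and an `outlier_trials` attribute (event rows
#'   that received an injected excursion).
#' @export
generate_recording <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  validate_synth_config(config)
  with_seed(config$seed, generate_recording_impl(config))
}

generate_recording_impl <- function(cfg) {
  fs <- cfg$sampling_rate
  chans <- cfg$channel_names
  nch <- length(chans)
  regions <- montage_regions(cfg$montage)

  ## trial schedule
  cond_seq <- sample(rep(cfg$conditions, each = cfg$n_trials_per_condition))
  n_trials <- length(cond_seq)
  itis <- stats::runif(n_trials, 1, 2)
  fixation <- 1.0
  pre_roll <- 2.0
  onsets <- numeric(n_trials)
  tcur <- pre_roll
  for (k in seq_len(n_trials)) {
    tcur <- tcur + fixation
    onsets[k] <- tcur
    tcur <- tcur + cfg$stimulus_duration + itis[k]
  }
  total_t <- tcur + 2.0
  n_samp <- ceiling(total_t * fs)
  onset_samp <- as.integer(round(onsets * fs)) + 1L

  ## background
  data <- matrix(0, nch, n_samp, dimnames = list(chans, NULL))
  for (i in seq_len(nch)) {
    data[i, ] <- cfg$noise$amplitude * pink_noise(n_samp, fs, cfg$noise$alpha)
  }

  add_burst <- function(ch, s0, wave) {
    idx <- s0 + seq_along(wave) - 1L
    keep <- idx >= 1L & idx <= n_samp
    data[ch, idx[keep]] <<- data[ch, idx[keep]] + wave[keep]
  }

  ## phase coupling
  for (cs in cfg$coupling_specs) {
    seed_ch <- intersect(regions[[cs$seed_region]], chans)
    if (!length(seed_ch)) stop("no seed-region channels synthesized")
    ramp <- 0.025
    t_rel <- seq(cs$window[1] - ramp, cs$window[2] + ramp, by = 1 / fs)
    env <- window_envelope(t_rel, cs$window[1], cs$window[2], ramp)
    trials <- which(cond_seq %in% cs$conditions)
    for (k in trials) {
      phi <- stats::runif(1, 0, 2 * pi)
      base_wave <- cs$amplitude * env * cos(2 * pi * cs$band_center * t_rel + phi)
      s0 <- onset_samp[k] + round(t_rel[1] * fs)
      for (ch in seed_ch) add_burst(ch, s0, base_wave)
      jit <- rvonmises(length(cs$target_channels), 0, cs$concentration)
      for (j in seq_along(cs$target_channels)) {
        wave <- cs$amplitude * env *
          cos(2 * pi * cs$band_center * t_rel + phi + cs$phase_lag + jit[j])
        add_burst(cs$target_channels[j], s0, wave)
      }
    }
  }

  ## band-power modulation: oscillation through the epoch span, envelope
  ## scaled by `gain` inside the window
  for (ps in cfg$power_specs) {
    f0 <- mean(ps$band)
    span <- c(cfg$epoch_window[1] - 0.15, cfg$epoch_window[2] + 0.15)
    t_rel <- seq(span[1], span[2], by = 1 / fs)
    span_env <- window_envelope(t_rel, span[1] + 0.05, span[2] - 0.05, 0.05)
    win_env <- 1 + (ps$gain - 1) * window_envelope(t_rel, ps$window[1],
                                                   ps$window[2])
    trials <- which(cond_seq %in% ps$conditions)
    for (k in trials) {
      phi <- stats::runif(1, 0, 2 * pi)
      wave <- ps$amplitude * span_env * win_env *
        cos(2 * pi * f0 * t_rel + phi)
      s0 <- onset_samp[k] + round(t_rel[1] * fs)
      for (ch in ps$channels) add_burst(ch, s0, wave)
    }
  }

  ## ERPs
  for (es in cfg$erp_specs) {
    t_rel <- seq(es$latency - 4 * es$width, es$latency + 4 * es$width,
                 by = 1 / fs)
    shape <- exp(-(t_rel - es$latency)^2 / (2 * es$width^2))
    trials <- which(cond_seq %in% es$conditions)
    for (ch in es$channels) {
      a <- if (length(es$amplitude) > 1L) es$amplitude[[ch]] else es$amplitude
      wave <- a * shape
      s0_rel <- round(t_rel[1] * fs)
      for (k in trials) add_burst(ch, onset_samp[k] + s0_rel, wave)
    }
  }

  ## blinks: 400 ms raised cosine, amplitude decaying with distance from
  ## the frontal pole (0, 1)
  blink_tc <- numeric(n_samp)
  if (cfg$blink_rate > 0) {
    n_blinks <- stats::rpois(1, cfg$blink_rate * total_t / 60)
    if (n_blinks > 0) {
      bt <- sort(stats::runif(n_blinks, 0, total_t - 0.5))
      tpl_t <- seq(0, 0.4, by = 1 / fs)
      tpl <- 0.5 * (1 - cos(2 * pi * tpl_t / 0.4))
      xy <- cfg$montage[match(chans, cfg$montage$channel), c("x", "y")]
      d <- sqrt(xy$x^2 + (xy$y - 1)^2)
      w <- exp(-d / 0.5)
      for (b in bt) {
        s0 <- round(b * fs) + 1L
        idx <- s0 + seq_along(tpl) - 1L
        keep <- idx <= n_samp
        blink_tc[idx[keep]] <- blink_tc[idx[keep]] + tpl[keep]
      }
      data <- data + cfg$blink_amplitude * (w %o% blink_tc)
    }
  }

  ## outlier trials: one >100 uV excursion on a random channel
  out_trials <- which(stats::runif(n_trials) < cfg$outlier_trial_fraction)
  for (k in out_trials) {
    ch <- sample(chans, 1)
    t_rel <- seq(0, 0.1, by = 1 / fs)
    wave <- 180 * 0.5 * (1 - cos(2 * pi * t_rel / 0.1))
    add_burst(ch, onset_samp[k] + round(0.45 * fs), wave)
  }

  events <- data.frame(sample = onset_samp, condition = cond_seq,
                       session = cfg$session, stringsAsFactors = FALSE)
  rec <- eeg_recording(data, fs, events)
  attr(rec, "truth") <- ground_truth(cfg)
  attr(rec, "outlier_trials") <- out_trials
  attr(rec, "blink_timecourse") <- blink_tc
  rec
}

#' Ground-truth tables for a synthetic configuration
#'
#' @param config a `synth_config`.
#' @return list of data frames `coupling` (channel, band_center, window
#'   start/end, condition, kappa, phase_lag), `power` (channel, band
#'   low/high, gain, window, condition) and `erp` (channel, latency,
#'   amplitude, condition), one row per injected (channel, condition) cell.
#' @export
ground_truth <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  crows <- list(); prows <- list(); erows <- list()
  for (cs in config$coupling_specs) {
    g <- expand.grid(channel = cs$target_channels,
                     condition = intersect(cs$conditions, config$conditions),
                     stringsAsFactors = FALSE)
    g$band_center <- cs$band_center
    g$window_start <- cs$window[1]; g$window_end <- cs$window[2]
    g$kappa <- cs$concentration; g$phase_lag <- cs$phase_lag
    crows[[length(crows) + 1L]] <- g
  }
  for (ps in config$power_specs) {
    g <- expand.grid(channel = ps$channels,
                     condition = intersect(ps$conditions, config$conditions),
                     stringsAsFactors = FALSE)
    g$band_low <- ps$band[1]; g$band_high <- ps$band[2]
    g$gain <- ps$gain
    g$window_start <- ps$window[1]; g$window_end <- ps$window[2]
    prows[[length(prows) + 1L]] <- g
  }
  for (es in config$erp_specs) {
    g <- expand.grid(channel = es$channels,
                     condition = intersect(es$conditions, config$conditions),
                     stringsAsFactors = FALSE)
    g$latency <- es$latency
    g$amplitude <- if (length(es$amplitude) > 1L) {
      unname(es$amplitude[g$channel])
    } else {
      es$amplitude
    }
    erows[[length(erows) + 1L]] <- g
  }
  empty <- function(cols) {
    as.data.frame(stats::setNames(rep(list(character(0)), length(cols)), cols))
  }
  list(
    coupling = if (length(crows)) do.call(rbind, crows) else
      empty(c("channel", "condition", "band_center", "window_start",
              "window_end", "kappa", "phase_lag")),
    power = if (length(prows)) do.call(rbind, prows) else
      empty(c("channel", "condition", "band_low", "band_high", "gain",
              "window_start", "window_end")),
    erp = if (length(erows)) do.call(rbind, erows) else
      empty(c("channel", "condition", "latency", "amplitude"))
  )
}
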
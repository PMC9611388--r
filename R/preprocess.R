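#' Epoch-structured EEG container
#'
#' @param data epoch x channel x time array, microvolts, with channel
#'   dimnames.
#' @param times sample times in seconds relative to stimulus onset.
#' @param sampling_rate Hz.
#' @param conditions condition label per epoch.
#' @param sessions session label per epoch (recycled if scalar).
#' @param baseline_window c(start, end) of the pre-stimulus baseline.
#' @param rejection_log data frame (epoch, condition, kept, reason)
#'   accumulated across epoching and rejection stages.
#' @return object of class `eeg_epochs`.
#' @export
eeg_epochs <- function(data, times, sampling_rate, conditions,
                       sessions = "S1", baseline_window = c(-0.2, 0),
                       rejection_log = NULL) {
  stopifnot(length(dim(data)) == 3L, dim(data)[3] == length(times),
            dim(data)[1] == length(conditions),
            all(diff(times) > 0), any(times == 0))
  if (baseline_window[1] < times[1] || baseline_window[2] > times[length(times)]) {
    stop("baseline_window must lie inside the epoch time range", call. = FALSE)
  }
  if (is.null(rejection_log)) {
    rejection_log <- data.frame(epoch = seq_len(dim(data)[1]),
                                condition = conditions, kept = TRUE,
                                reason = "", stringsAsFactors = FALSE)
  }
  structure(list(data = data, times = times, sampling_rate = sampling_rate,
                 channels = dimnames(data)[[2]],
                 conditions = conditions,
                 sessions = rep_len(sessions, length(conditions)),
                 baseline_window = baseline_window,
                 rejection_log = rejection_log),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat("<eeg_epochs> ", d[1], " epochs x ", d[2], " channels x ", d[3],
      " samples @ ", x$sampling_rate, " Hz, t in [",
      round(x$times[1], 3), ", ", round(x$times[length(x$times)], 3),
      "] s\n", sep = "")
  cat("conditions:", paste(sprintf("%s=%d", names(table(x$conditions)),
                                   table(x$conditions)), collapse = ", "), "\n")
  invisible(x)
}

#' Common-average re-referencing
#'
#' Subtracts the instantaneous mean across channels, so that at every sample
#' the channel mean is zero.  Idempotent.
#'
#' @param rec an [eeg_recording] (or a channels x samples matrix).
#' @return object of the same type, re-referenced.
#' @export
rereference_common_average <- function(rec) {
  x <- if (inherits(rec, "eeg_recording")) rec$data else rec
  if (nrow(x) < 2L) {
    stop("common-average reference needs at least 2 channels", call. = FALSE)
  }
  x <- sweep(x, 2L, colMeans(x))
  if (inherits(rec, "eeg_recording")) {
    rec$data <- x
    rec
  } else {
    x
  }
}

# Frequency response of the band mask: raised-cosine transitions of width
# `tw` Hz centred on each cut-off.
fft_band_gain <- function(f, low, high, tw = 0.5) {
  g <- numeric(length(f))
  g[f >= low + tw / 2 & f <= high - tw / 2] <- 1
  lo <- f > low - tw / 2 & f < low + tw / 2
  g[lo] <- 0.5 * (1 - cos(pi * (f[lo] - (low - tw / 2)) / tw))
  hi <- f > high - tw / 2 & f < high + tw / 2
  g[hi] <- 0.5 * (1 + cos(pi * (f[hi] - (high - tw / 2)) / tw))
  g
}

# Filter rows of a channels x samples matrix in the frequency domain.
fft_bandpass_matrix <- function(x, srate, low, high, transition = 0.5) {
  padded <- fft_length_pad(x)
  xp <- padded$x
  n <- ncol(xp)
  f <- seq(0, srate, length.out = n + 1L)[seq_len(n)]
  f <- pmin(f, srate - f)
  g <- fft_band_gain(f, low, high, transition)
  X <- stats::mvfft(t(xp))
  y <- t(Re(stats::mvfft(X * g, inverse = TRUE)))[, seq_len(padded$n),
                                                  drop = FALSE] / n
  dimnames(y) <- dimnames(x)
  y
}

#' Zero-phase frequency-domain bandpass filter
#'
#' Forward FFT, raised-cosine taper outside `[low, high]` (transition width
#' 0.5 Hz at each edge), inverse FFT.  The filter has exactly zero group
#' delay; a sinusoid inside the passband is preserved in amplitude and
#' phase.  Epoch objects are mirror-padded 200 ms per side before filtering
#' to suppress wrap-around transients.
#'
#' @param x an [eeg_recording], [eeg_epochs], or channels x samples matrix.
#' @param low,high cut-off frequencies, Hz (defaults 1 and 30).
#' @param transition raised-cosine transition width in Hz.
#' @param sampling_rate required when `x` is a bare matrix.
#' @return filtered object of the same type.
#' @export
bandpass_zero_phase <- function(x, low = 1, high = 30, transition = 0.5,
                                sampling_rate = NULL) {
  UseMethod("bandpass_zero_phase")
}

check_band_edges <- function(low, high, srate) {
  if (!(low > 0 && low < high)) {
    stop("need 0 < low < high", call. = FALSE)
  }
  if (high >= srate / 2) {
    stop("high cut-off (", high, " Hz) must be below the Nyquist frequency (",
         srate / 2, " Hz)", call. = FALSE)
  }
}

#' @export
bandpass_zero_phase.eeg_recording <- function(x, low = 1, high = 30,
                                              transition = 0.5,
                                              sampling_rate = NULL) {
  check_band_edges(low, high, x$sampling_rate)
  x$data <- fft_bandpass_matrix(x$data, x$sampling_rate, low, high, transition)
  x
}

#' @export
bandpass_zero_phase.eeg_epochs <- function(x, low = 1, high = 30,
                                           transition = 0.5,
                                           sampling_rate = NULL) {
  check_band_edges(low, high, x$sampling_rate)
  pad <- round(0.2 * x$sampling_rate)
  nt <- length(x$times)
  for (e in seq_len(dim(x$data)[1])) {
    m <- mirror_pad(x$data[e, , , drop = TRUE], pad)
    if (is.null(dim(m))) m <- matrix(m, nrow = 1L)
    filt <- fft_bandpass_matrix(m, x$sampling_rate, low, high, transition)
    x$data[e, , ] <- filt[, (pad + 1L):(pad + nt), drop = FALSE]
  }
  x
}

#' @export
bandpass_zero_phase.matrix <- function(x, low = 1, high = 30,
                                       transition = 0.5,
                                       sampling_rate = NULL) {
  stopifnot(!is.null(sampling_rate))
  check_band_edges(low, high, sampling_rate)
  fft_bandpass_matrix(x, sampling_rate, low, high, transition)
}

#' @export
bandpass_zero_phase.numeric <- function(x, low = 1, high = 30,
                                        transition = 0.5,
                                        sampling_rate = NULL) {
  drop(bandpass_zero_phase(matrix(x, nrow = 1L), low, high, transition,
                           sampling_rate))
}

#' Extract stimulus-locked epochs
#'
#' One epoch per event, from `tmin` to `tmax` seconds around onset.  Events
#' too close to a recording edge are dropped and logged.
#'
#' @param rec an [eeg_recording] with events.
#' @param tmin,tmax epoch window in seconds relative to onset (defaults
#'   -0.2 and +1.0).
#' @param baseline_window baseline interval recorded on the result.
#' @return an [eeg_epochs]; its `rejection_log` records edge-dropped events.
#' @export
extract_epochs <- function(rec, tmin = -0.2, tmax = 1.0,
                           baseline_window = c(-0.2, 0)) {
  stopifnot(inherits(rec, "eeg_recording"), tmin < tmax)
  fs <- rec$sampling_rate
  rel <- round(tmin * fs):round(tmax * fs)
  times <- rel / fs
  n <- ncol(rec$data)
  ev <- rec$events
  first <- ev$sample + rel[1]
  last <- ev$sample + rel[length(rel)]
  ok <- first >= 1L & last <= n
  log <- data.frame(epoch = seq_len(nrow(ev)), condition = ev$condition,
                    kept = ok,
                    reason = ifelse(ok, "", "event too close to recording edge"),
                    stringsAsFactors = FALSE)
  keep <- which(ok)
  data <- array(0, dim = c(length(keep), nrow(rec$data), length(rel)),
                dimnames = list(NULL, rec$channels, NULL))
  for (i in seq_along(keep)) {
    k <- keep[i]
    data[i, , ] <- rec$data[, (ev$sample[k] + rel[1]):(ev$sample[k] + rel[length(rel)])]
  }
  eeg_epochs(data, times, fs, ev$condition[keep], ev$session[keep],
             baseline_window, rejection_log = log)
}

#' Amplitude-based trial rejection
#'
#' Drops every epoch in which any channel's absolute potential strictly
#' exceeds `threshold` (default 100 uV).
#'
#' @param epochs an [eeg_epochs].
#' @param threshold rejection threshold in uV.
#' @return the surviving epochs; the `rejection_log` is extended and a
#'   `survival_fraction` attribute reports kept / tested.
#' @export
reject_amplitude <- function(epochs, threshold = 100) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  n <- dim(epochs$data)[1]
  bad <- vapply(seq_len(n),
                function(e) any(abs(epochs$data[e, , ]) > threshold),
                logical(1))
  log <- epochs$rejection_log
  kept_rows <- which(log$kept)
  stopifnot(length(kept_rows) == n)
  log$kept[kept_rows[bad]] <- FALSE
  log$reason[kept_rows[bad]] <- sprintf("amplitude > %g uV", threshold)
  out <- epochs
  out$data <- epochs$data[!bad, , , drop = FALSE]
  out$conditions <- epochs$conditions[!bad]
  out$sessions <- epochs$sessions[!bad]
  out$rejection_log <- log
  attr(out, "survival_fraction") <- if (n) sum(!bad) / n else NA_real_
  if (n && all(bad)) warning("all epochs rejected", call. = FALSE)
  out
}

#' Frequency band specification
#' @param name band label.
#' @param low,high band edges in Hz.
#' @export
band_spec <- function(name, low, high) {
  stopifnot(is.character(name), low > 0, low < high)
  structure(list(name = name, low = low, high = high), class = "band_spec")
}

#' The four canonical analysis bands
#'
#' delta 1-3 Hz, theta 4-7 Hz, alpha 8-13 Hz, beta 14-30 Hz.
#' @return named list of [band_spec] objects.
#' @export
default_bands <- function() {
  list(delta = band_spec("delta", 1, 3),
       theta = band_spec("theta", 4, 7),
       alpha = band_spec("alpha", 8, 13),
       beta  = band_spec("beta", 14, 30))
}

#' Split into frequency bands
#'
#' Zero-phase filtered copies of the input, one per band; epoch/label
#' structure preserved.
#'
#' @param x an [eeg_recording] or [eeg_epochs].
#' @param bands named list of [band_spec] objects (default [default_bands()]).
#' @return named list of filtered objects.
#' @export
filter_bands <- function(x, bands = default_bands()) {
  stopifnot(all(vapply(bands, inherits, logical(1), "band_spec")))
  out <- lapply(bands, function(b) bandpass_zero_phase(x, b$low, b$high))
  names(out) <- vapply(bands, `[[`, character(1), "name")
  out
}
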
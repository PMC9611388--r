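# Default cycle count for the Morlet family: linear ramp from 3 cycles at
# 1 Hz to 8 cycles at 30 Hz, clipped below at 2.
default_n_cycles <- function(freqs) {
  pmax(2, 3 + 5 * (freqs - 1) / 29)
}

#' Continuous Morlet wavelet transform (magnitudes)
#'
#' Complex Morlet convolution implemented as a Gaussian frequency-domain
#' (Gabor) filter on the analytic spectrum, mirror-padded 0.5 s per side.
#' The transform is normalized so that a pure sinusoid of amplitude A at a
#' target frequency has ridge magnitude A (in the input's units).
#'
#' @param x channels x time matrix (one epoch) or an [eeg_epochs].
#' @param sampling_rate Hz (taken from epoch objects).
#' @param freqs analysis frequencies, Hz; must lie in (0, Nyquist).
#' @param n_cycles cycles per frequency (scalar, vector, or NULL for the
#'   default 3-to-8 ramp over 1-30 Hz).
#' @return for a matrix, a channels x freq x time array of magnitudes with
#'   an `edge` attribute (freq x time logical, TRUE where the sample lies
#'   within two wavelet standard deviations of an epoch edge); for epochs,
#'   an epoch x channel x freq x time array.
#' @export
morlet_tfr <- function(x, sampling_rate = NULL, freqs, n_cycles = NULL) {
  if (inherits(x, "eeg_epochs")) {
    d <- dim(x$data)
    out <- array(0, c(d[1], d[2], length(freqs), d[3]),
                 dimnames = list(NULL, x$channels, NULL, NULL))
    for (e in seq_len(d[1])) {
      m <- morlet_tfr(x$data[e, , , drop = TRUE], x$sampling_rate, freqs,
                      n_cycles)
      if (e == 1L) attr(out, "edge") <- attr(m, "edge")
      out[e, , , ] <- m
    }
    return(out)
  }
  stopifnot(!is.null(sampling_rate), is.matrix(x))
  if (any(freqs <= 0) || any(freqs >= sampling_rate / 2)) {
    stop("analysis frequencies must lie in (0, Nyquist)", call. = FALSE)
  }
  n_cycles <- if (is.null(n_cycles)) default_n_cycles(freqs) else
    rep_len(n_cycles, length(freqs))
  nt <- ncol(x); nch <- nrow(x)
  pad <- round(0.5 * sampling_rate)
  xp <- mirror_pad(x, pad)
  pad <- min(pad, nt - 1L)
  padded <- fft_length_pad(xp)
  xp <- padded$x
  L <- ncol(xp)
  fgrid <- seq(0, sampling_rate, length.out = L + 1L)[seq_len(L)]
  X <- stats::mvfft(t(xp))   # L x nch
  out <- array(0, c(nch, length(freqs), nt),
               dimnames = list(rownames(x), NULL, NULL))
  edge <- matrix(FALSE, length(freqs), nt)
  half <- L %/% 2
  for (j in seq_along(freqs)) {
    f0 <- freqs[j]
    sig_t <- n_cycles[j] / (2 * pi * f0)
    g <- numeric(L)
    pos <- seq_len(half + 1L)
    g[pos] <- 2 * exp(-((fgrid[pos] - f0) * 2 * pi * sig_t)^2 / 2)
    g[1L] <- 0
    tfr <- stats::mvfft(X * g, inverse = TRUE) / L   # L x nch, complex
    out[, j, ] <- t(Mod(tfr[(pad + 1L):(pad + nt), , drop = FALSE]))
    ne <- min(nt, ceiling(2 * sig_t * sampling_rate))
    if (ne > 0) edge[j, c(seq_len(ne), nt - seq_len(ne) + 1L)] <- TRUE
  }
  attr(out, "edge") <- edge
  out
}

#' Event-related spectral perturbation (ERSP)
#'
#' Per epoch, channel and frequency: `10 * log10(u / baseline)` where `u`
#' is the Morlet wavelet-coefficient magnitude and `baseline` its
#' pre-stimulus average at that frequency; epochs are averaged afterwards.
#' The default follows the magnitude ratio literally; `convention =
#' "power"` squares the magnitudes first (i.e. a 20 log10 scale on
#' amplitude).  The monotone relation between the two leaves
#' baseline-relative screening unchanged.
#'
#' @param epochs an [eeg_epochs].
#' @param freqs analysis frequencies, Hz.
#' @param baseline_window c(start, end) s; defaults to the epochs'
#'   baseline.
#' @param n_cycles see [morlet_tfr].
#' @param convention `"magnitude"` (default) or `"power"`.
#' @param channels optional channel subset.
#' @param conditions optional condition subset of epochs to include.
#' @return object of class `ersp_map`: `values` (channel x freq x time, dB),
#'   `freqs`, `times`, `baseline_window`, `n_epochs`, `baseline` (channel x
#'   freq mean baseline magnitude), `edge` (freq x time flags), `convention`.
#' @export
ersp <- function(epochs, freqs, baseline_window = NULL, n_cycles = NULL,
                 convention = c("magnitude", "power"), channels = NULL,
                 conditions = NULL) {
  convention <- match.arg(convention)
  stopifnot(inherits(epochs, "eeg_epochs"))
  baseline_window <- baseline_window %||% epochs$baseline_window
  if (baseline_window[1] < epochs$times[1] ||
      baseline_window[2] > epochs$times[length(epochs$times)]) {
    stop("baseline window must lie inside the epoch", call. = FALSE)
  }
  keep_ep <- if (is.null(conditions)) seq_along(epochs$conditions) else
    which(epochs$conditions %in% conditions)
  if (!length(keep_ep)) stop("no epochs in the requested conditions",
                             call. = FALSE)
  channels <- channels %||% epochs$channels
  ch_idx <- match(channels, epochs$channels)
  if (anyNA(ch_idx)) {
    stop("channels not present: ",
         paste(channels[is.na(ch_idx)], collapse = ", "), call. = FALSE)
  }
  bsel <- epochs$times >= baseline_window[1] & epochs$times <= baseline_window[2]
  bidx <- which(bsel)
  acc <- array(0, c(length(ch_idx), length(freqs), length(epochs$times)),
               dimnames = list(channels, NULL, NULL))
  bacc <- matrix(0, length(ch_idx), length(freqs),
                 dimnames = list(channels, NULL))
  edge <- NULL
  zero_base <- FALSE
  for (e in keep_ep) {
    m <- matrix(epochs$data[e, ch_idx, ], nrow = length(ch_idx),
                dimnames = list(channels, NULL))
    u <- morlet_tfr(m, epochs$sampling_rate, freqs, n_cycles)
    if (is.null(edge)) {
      edge <- attr(u, "edge")
      # per-frequency baseline samples: drop those inside the wavelet edge
      # zone, but always retain at least the later half of the baseline
      base_idx <- lapply(seq_along(freqs), function(j) {
        good <- bidx[!edge[j, bidx]]
        if (length(good) < ceiling(length(bidx) / 2)) {
          good <- bidx[seq.int(length(bidx) - ceiling(length(bidx) / 2) + 1L,
                               length(bidx))]
        }
        good
      })
    }
    if (convention == "power") u <- u^2
    ub <- vapply(seq_along(freqs), function(j)
      apply(u[, j, base_idx[[j]], drop = FALSE], 1L, mean),
      numeric(length(ch_idx)))
    ub <- matrix(ub, nrow = length(ch_idx))
    if (any(ub == 0)) zero_base <- TRUE
    db <- 10 * log10(sweep(u, c(1, 2), ub, "/"))
    db[!is.finite(db)] <- NaN
    acc <- acc + db
    bacc <- bacc + ub
  }
  if (zero_base) warning("zero baseline magnitude; affected cells set to NaN",
                         call. = FALSE)
  structure(list(values = acc / length(keep_ep), freqs = freqs,
                 times = epochs$times, baseline_window = baseline_window,
                 n_epochs = length(keep_ep),
                 baseline = bacc / length(keep_ep), edge = edge,
                 convention = convention),
            class = "ersp_map")
}

#' @export
print.ersp_map <- function(x, ...) {
  cat("<ersp_map> ", dim(x$values)[1], " channels x ", length(x$freqs),
      " freqs x ", length(x$times), " times (", x$convention,
      " convention, ", x$n_epochs, " epochs); range [",
      round(min(x$values, na.rm = TRUE), 2), ", ",
      round(max(x$values, na.rm = TRUE), 2), "] dB\n", sep = "")
  invisible(x)
}

#' Hjorth-style finite-difference surface Laplacian
#'
#' Each channel's value minus the inverse-distance-weighted mean of its
#' `k` nearest neighbours on the montage disc.  Sharpens focal activity and
#' suppresses spatially broad (volume-conducted) components; annihilates a
#' spatially uniform topography exactly.
#'
#' @param values named numeric vector (one value per channel) or a
#'   channels x m matrix with rownames; typically ERSP values.
#' @param montage an [eeg_montage] covering all channels of `values`.
#' @param k number of neighbours (default 4).
#' @return object of the same shape, Laplacian-transformed.
#' @export
surface_laplacian <- function(values, montage, k = 4L) {
  one_d <- is.null(dim(values))
  vm <- if (one_d) matrix(values, ncol = 1L,
                          dimnames = list(names(values), NULL)) else values
  chans <- rownames(vm)
  if (is.null(chans)) stop("`values` must carry channel names", call. = FALSE)
  idx <- match(chans, montage$channel)
  if (anyNA(idx)) {
    stop("montage positions missing for: ",
         paste(chans[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  sub <- montage[idx, ]
  if (nrow(sub) - 1L < k) {
    warning("fewer than k = ", k, " neighbours available; using ",
            nrow(sub) - 1L, call. = FALSE)
  }
  nb <- montage_neighbors(sub, k)
  out <- vm
  for (i in seq_len(nrow(vm))) {
    w <- nb[[i]]$w
    out[i, ] <- vm[i, ] - colSums(vm[nb[[i]]$idx, , drop = FALSE] * w) / sum(w)
  }
  if (one_d) stats::setNames(out[, 1L], chans) else out
}

#' Mu-rhythm ERD/ERS time course over a region of interest
#'
#' Averages an [ersp] map over the ROI channels and the mu band rows and
#' reports the most negative (event-related desynchronization) and most
#' positive (event-related synchronization) excursions with their times.
#' Condition contrasts at the ERS window are tested separately with
#' [permutation_test_independent] on per-participant window means.
#'
#' @param ersp_map an `ersp_map` containing the ROI channels.
#' @param roi_channels channel labels, e.g. the left somatosensory set
#'   C5, CP3, CP5.
#' @param band c(low, high) Hz (default mu, 8-13).
#' @param post_only search excursions at t >= 0 only (default TRUE).
#' @return list with `times`, `timecourse` (dB), `erd` and `ers`
#'   (each value + time).
#' @export
mu_erd_ers <- function(ersp_map, roi_channels, band = c(8, 13),
                       post_only = TRUE) {
  stopifnot(inherits(ersp_map, "ersp_map"))
  have <- rownames(ersp_map$values) %||% dimnames(ersp_map$values)[[1]]
  missing <- setdiff(roi_channels, dimnames(ersp_map$values)[[1]])
  if (length(missing)) {
    stop("ROI channel(s) missing from ERSP map: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  fsel <- ersp_map$freqs >= band[1] & ersp_map$freqs <= band[2]
  if (!any(fsel)) stop("no analysis frequencies inside the band", call. = FALSE)
  sub <- ersp_map$values[roi_channels, fsel, , drop = FALSE]
  tc <- apply(sub, 3L, mean, na.rm = TRUE)
  # excursion search skips samples inside the wavelet edge zone, where the
  # taper decay mimics desynchronization
  valid <- rep(TRUE, length(ersp_map$times))
  if (!is.null(ersp_map$edge)) {
    valid <- !apply(ersp_map$edge[fsel, , drop = FALSE], 2L, any)
    if (!any(valid)) valid <- rep(TRUE, length(ersp_map$times))
  }
  sel <- which(valid & (!post_only | ersp_map$times >= 0))
  i_erd <- sel[which.min(tc[sel])]
  i_ers <- sel[which.max(tc[sel])]
  list(times = ersp_map$times, timecourse = tc, valid = valid,
       erd = list(value = tc[i_erd], time = ersp_map$times[i_erd]),
       ers = list(value = tc[i_ers], time = ersp_map$times[i_ers]))
}

# Local maxima with a prominence criterion: prominence of a peak is its
# height above the higher of the two bracketing minima (up to the nearest
# higher point on each side, or the series end).
find_peaks <- function(x, prominence = 0) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  cand <- which(diff(sign(diff(x))) < 0) + 1L
  keep <- vapply(cand, function(i) {
    left <- x[seq_len(i - 1L)]
    higher_l <- which(left > x[i])
    lmin <- min(left[seq.int(from = if (length(higher_l)) max(higher_l) else 1L,
                             to = i - 1L)])
    right <- x[(i + 1L):n]
    higher_r <- which(right > x[i])
    rmin <- min(right[seq.int(from = 1L,
                              to = if (length(higher_r)) min(higher_r) else
                                length(right))])
    (x[i] - max(lmin, rmin)) >= prominence
  }, logical(1))
  cand[keep]
}

#' Parieto-occipital ERP lateralization (PO7 - PO8)
#'
#' Baseline-corrects every epoch, forms per-condition grand-average ERPs at
#' the left and right electrodes, and analyses the left-minus-right
#' difference waveform: per-condition means +/- standard error in the
#' analysis window, lateralization peaks (local maxima of the rectified
#' difference above a prominence threshold), and a one-way ANOVA with
#' Tukey pairwise comparisons of the per-epoch window means across
#' conditions.
#'
#' @param epochs an [eeg_epochs] containing both electrodes and condition
#'   labels.
#' @param left,right electrode labels (defaults PO7, PO8).
#' @param window c(start, end) s of the lateralization window (default
#'   0.246-0.300).
#' @param prominence peak prominence threshold in uV (default 0.5).
#' @param conditions conditions to analyse (default: all present).
#' @return object of class `erp_lateralization`: `times`, `difference`
#'   (condition x time matrix of left - right grand averages),
#'   `window_stats` (condition, mean, se, n), `peaks` (list of peak times
#'   per condition), `anova` (from [anova_one_way]).
#' @export
erp_lateralization <- function(epochs, left = "PO7", right = "PO8",
                               window = c(0.246, 0.300), prominence = 0.5,
                               conditions = NULL) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  for (ch in c(left, right)) {
    if (!(ch %in% epochs$channels)) {
      stop("electrode ", ch, " not present", call. = FALSE)
    }
  }
  conditions <- conditions %||% sort(unique(epochs$conditions))
  missing <- setdiff(conditions, epochs$conditions)
  if (length(missing)) {
    stop("condition(s) absent from epochs: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  il <- match(left, epochs$channels); ir <- match(right, epochs$channels)
  bsel <- epochs$times >= epochs$baseline_window[1] &
    epochs$times <= epochs$baseline_window[2]
  wsel <- epochs$times >= window[1] & epochs$times <= window[2]
  if (!any(wsel)) stop("analysis window contains no samples", call. = FALSE)
  ldat <- epochs$data[, il, , drop = TRUE]
  rdat <- epochs$data[, ir, , drop = TRUE]
  if (is.null(dim(ldat))) { ldat <- matrix(ldat, 1L); rdat <- matrix(rdat, 1L) }
  ldat <- ldat - rowMeans(ldat[, bsel, drop = FALSE])
  rdat <- rdat - rowMeans(rdat[, bsel, drop = FALSE])
  dwave <- matrix(NA_real_, length(conditions), length(epochs$times),
                  dimnames = list(conditions, NULL))
  stats_df <- data.frame(condition = conditions, mean = NA_real_,
                         se = NA_real_, n = NA_integer_)
  peaks <- vector("list", length(conditions)); names(peaks) <- conditions
  groups <- vector("list", length(conditions)); names(groups) <- conditions
  post <- epochs$times >= 0
  for (ci in seq_along(conditions)) {
    sel <- epochs$conditions == conditions[ci]
    d_ep <- ldat[sel, , drop = FALSE] - rdat[sel, , drop = FALSE]
    dwave[ci, ] <- colMeans(d_ep)
    wm <- rowMeans(d_ep[, wsel, drop = FALSE])
    stats_df$mean[ci] <- mean(wm)
    stats_df$se[ci] <- stats::sd(wm) / sqrt(length(wm))
    stats_df$n[ci] <- length(wm)
    groups[[ci]] <- wm
    pk <- find_peaks(abs(dwave[ci, post]), prominence)
    peaks[[ci]] <- epochs$times[post][pk]
  }
  an <- if (length(conditions) >= 2L &&
            all(vapply(groups, length, integer(1)) >= 2L)) {
    anova_one_way(groups)
  } else {
    NULL
  }
  structure(list(times = epochs$times, difference = dwave,
                 window = window, window_stats = stats_df, peaks = peaks,
                 anova = an, left = left, right = right),
            class = "erp_lateralization")
}

#' @export
print.erp_lateralization <- function(x, ...) {
  cat("<erp_lateralization> ", x$left, " - ", x$right, ", window [",
      x$window[1], ", ", x$window[2], "] s\n", sep = "")
  print(x$window_stats, row.names = FALSE)
  if (!is.null(x$anova)) {
    cat("one-way ANOVA: F =", signif(x$anova$F, 4),
        ", p =", signif(x$anova$p, 4), "\n")
  }
  invisible(x)
}
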
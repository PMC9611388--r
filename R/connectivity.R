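#' Fused occipital seed channel
#'
#' Arithmetic mean of the occipital seed electrodes' time series (signal
#' level fusion, before any phase extraction), per epoch.
#'
#' @param epochs an [eeg_epochs].
#' @param montage an [eeg_montage] whose `seed_region` group names the seed
#'   electrodes (default `OCC_SEED` = Oz, O1, O2, POz, PO3, PO4).
#' @param seed_region region-group name.
#' @return epochs x time matrix of the virtual seed channel.
#' @export
fuse_occipital <- function(epochs, montage, seed_region = "OCC_SEED") {
  stopifnot(inherits(epochs, "eeg_epochs"))
  seed_ch <- montage_regions(montage)[[seed_region]]
  if (is.null(seed_ch)) {
    stop("montage has no region group ", seed_region, call. = FALSE)
  }
  missing <- setdiff(seed_ch, epochs$channels)
  if (length(missing)) {
    stop("seed electrode(s) missing from epochs: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  idx <- match(seed_ch, epochs$channels)
  n_ep <- dim(epochs$data)[1]
  out <- matrix(0, n_ep, length(epochs$times))
  for (e in seq_len(n_ep)) {
    out[e, ] <- colMeans(epochs$data[e, idx, , drop = FALSE][1, , ])
  }
  out
}

#' Instantaneous phase via the analytic signal
#'
#' Phase of the Hilbert-transform analytic signal, in (-pi, pi].  Intended
#' for band-limited (narrowband) input; broadband input yields phases
#' without a clean interpretation.  Each epoch is mirror-padded `pad`
#' seconds per side before the transform and the pads are discarded, so
#' edge transients do not contaminate the pre-stimulus baseline.
#'
#' @param x numeric vector, epochs x time matrix, or [eeg_epochs].
#' @param sampling_rate Hz (taken from the object when `x` is epochs).
#' @param pad mirror padding in seconds (default 0.2).
#' @return phases with the same shape as the input (for epoch objects, an
#'   epochs x channel x time array).
#' @export
instantaneous_phase <- function(x, sampling_rate = NULL, pad = 0.2) {
  if (inherits(x, "eeg_epochs")) {
    d <- dim(x$data)
    out <- array(0, d, dimnames = dimnames(x$data))
    for (ch in seq_len(d[2])) {
      out[, ch, ] <- instantaneous_phase(x$data[, ch, , drop = TRUE],
                                         x$sampling_rate, pad)
    }
    return(out)
  }
  stopifnot(!is.null(sampling_rate))
  one_d <- is.null(dim(x))
  xm <- if (one_d) matrix(x, nrow = 1L) else x
  if (any(apply(xm, 1L, stats::sd) < 1e-12)) {
    stop("constant (zero-bandwidth) input has no defined instantaneous phase",
         call. = FALSE)
  }
  np <- round(pad * sampling_rate)
  n <- ncol(xm)
  padded <- mirror_pad(xm, np)
  np <- min(np, n - 1L)
  ph <- Arg(analytic_signal(padded))[, (np + 1L):(np + n), drop = FALSE]
  if (one_d) ph[1L, ] else ph
}

#' Phase-locking value over time
#'
#' At each time point, the across-epoch consistency of the phase difference
#' between seed and target:
#' \deqn{PLV_t = \left[\frac{1}{n}\sum_k \cos\Delta\theta_{k,t}\right]^2 +
#'              \left[\frac{1}{n}\sum_k \sin\Delta\theta_{k,t}\right]^2}
#' i.e. the *squared* resultant length of the phase differences (default
#' convention `"squared"`, whose null expectation for uniform phases is
#' 1/n).  `convention = "sqrt"` returns the conventional mean resultant
#' length instead.  Both lie in [0, 1] and are symmetric in the two inputs.
#'
#' @param seed_phases,target_phases epochs x time phase matrices (radians)
#'   with identical dimensions.
#' @param convention `"squared"` (default) or `"sqrt"`.
#' @param times optional time axis carried on the result.
#' @param band optional [band_spec] carried on the result.
#' @param seed_label,target_label optional labels.
#' @return object of class `plv_series`: list with `values` (one PLV per
#'   time point), `n_epochs`, `times`, `band`, `convention`, labels.
#' @export
plv_series <- function(seed_phases, target_phases,
                       convention = c("squared", "sqrt"),
                       times = NULL, band = NULL,
                       seed_label = "seed", target_label = "target") {
  convention <- match.arg(convention)
  if (is.null(dim(seed_phases))) seed_phases <- matrix(seed_phases, nrow = 1L)
  if (is.null(dim(target_phases))) target_phases <- matrix(target_phases, nrow = 1L)
  if (!all(dim(seed_phases) == dim(target_phases))) {
    stop("seed and target phase matrices must have identical dimensions",
         call. = FALSE)
  }
  n <- nrow(seed_phases)
  if (n < 2L) stop("PLV needs at least 2 epochs", call. = FALSE)
  d <- seed_phases - target_phases
  v <- colMeans(cos(d))^2 + colMeans(sin(d))^2
  if (convention == "sqrt") v <- sqrt(v)
  structure(list(values = v, n_epochs = n, times = times, band = band,
                 convention = convention, seed = seed_label,
                 target = target_label),
            class = "plv_series")
}

#' @export
print.plv_series <- function(x, ...) {
  cat("<plv_series> ", x$seed, " -> ", x$target, ", ", length(x$values),
      " time points from ", x$n_epochs, " epochs (", x$convention,
      " convention); range [", round(min(x$values), 4), ", ",
      round(max(x$values), 4), "]\n", sep = "")
  invisible(x)
}

#' Occipital-seeded PLV for every non-seed electrode
#'
#' Fuses the occipital seed ([fuse_occipital]), extracts instantaneous
#' phases of seed and targets, and computes one PLV time series per
#' remaining electrode.
#'
#' @inheritParams fuse_occipital
#' @param convention PLV convention, see [plv_series].
#' @return electrodes x time matrix of PLVs with attributes `times`,
#'   `n_epochs`, `convention`.
#' @export
occipital_plv <- function(epochs, montage, seed_region = "OCC_SEED",
                          convention = "squared") {
  fused <- fuse_occipital(epochs, montage, seed_region)
  seed_ph <- instantaneous_phase(fused, epochs$sampling_rate)
  seed_ch <- montage_regions(montage)[[seed_region]]
  targets <- setdiff(epochs$channels, seed_ch)
  out <- matrix(NA_real_, length(targets), length(epochs$times),
                dimnames = list(targets, NULL))
  for (ch in targets) {
    tp <- instantaneous_phase(epochs$data[, match(ch, epochs$channels), ,
                                          drop = TRUE],
                              epochs$sampling_rate)
    out[ch, ] <- plv_series(seed_ph, tp, convention)$values
  }
  attr(out, "times") <- epochs$times
  attr(out, "n_epochs") <- dim(epochs$data)[1]
  attr(out, "convention") <- convention
  out
}

#' Bootstrap grand mean of baseline PLVs
#'
#' Draws baseline-window values with replacement (same size as the
#' baseline), averages, repeats `n_boot` times and returns the grand mean
#' of the bootstrap averages -- the per-series control value of the ePLV
#' screen.
#'
#' @param x a `plv_series`, a numeric vector of PLVs with a matching
#'   `times`, or a numeric vector of baseline values directly
#'   (`times = NULL`).
#' @param times time axis of `x` when it is a bare vector.
#' @param baseline_window c(start, end) seconds defining the baseline.
#' @param n_boot bootstrap replicates (default 10000).
#' @param seed integer seed, or NULL for the caller's RNG stream.
#' @return the grand bootstrap mean (scalar).
#' @export
bootstrap_baseline_mean <- function(x, times = NULL,
                                    baseline_window = c(-0.2, 0),
                                    n_boot = 10000, seed = NULL) {
  if (inherits(x, "plv_series")) {
    times <- x$times
    x <- x$values
  }
  base <- if (is.null(times)) {
    x
  } else {
    x[times >= baseline_window[1] & times <= baseline_window[2]]
  }
  if (length(base) < 2L) {
    stop("baseline window must contain at least 2 time samples", call. = FALSE)
  }
  nb <- length(base)
  with_seed(seed, {
    draws <- matrix(base[sample.int(nb, nb * n_boot, replace = TRUE)],
                    nrow = n_boot)
    mean(rowMeans(draws))
  })
}

#' Screen PLVs into effective PLVs (ePLVs)
#'
#' The two-step bootstrap-against-baseline procedure: (i) for every
#' participant and electrode, the baseline PLVs are bootstrap-resampled to
#' a grand mean ([bootstrap_baseline_mean]); (ii) at every (electrode,
#' time) cell the across-participant PLVs are compared with the
#' per-participant baseline grand means by the one-tailed paired bootstrap
#' test ([bootstrap_paired_test], PLV > baseline).  Cells with p' <= alpha
#' form the ePLV mask.  No multiple-comparison correction is applied.
#'
#' @param plv_list list with one electrodes x time PLV matrix per
#'   participant (identical dimnames/row order), e.g. from
#'   [occipital_plv].
#' @param times time axis; taken from the first matrix's `times` attribute
#'   when NULL.
#' @param baseline_window c(start, end) seconds of the pre-stimulus
#'   baseline.
#' @param alpha significance level.
#' @param n_boot bootstrap replicates for both steps.
#' @param seed integer seed for the whole screen.
#' @param time_stride test every `time_stride`-th post-baseline sample
#'   (PLV series are smooth; striding keeps the screen tractable).
#' @param direction `"greater"` tests PLV above baseline (default),
#'   `"less"` below.
#' @return object of class `eplv_mask`: `significant` and `p` matrices
#'   (electrodes x screened times), `times` (screened time axis),
#'   `baseline_mean` (participants x electrodes), `alpha`, `n_boot`,
#'   `seed`.
#' @export
screen_eplv <- function(plv_list, times = NULL, baseline_window = c(-0.2, 0),
                        alpha = 0.05, n_boot = 10000, seed = NULL,
                        time_stride = 1L, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  if (length(plv_list) < 2L) {
    stop("ePLV screening needs at least 2 participants", call. = FALSE)
  }
  if (!(alpha >= 0 && alpha <= 1)) stop("alpha must be in [0, 1]", call. = FALSE)
  times <- times %||% attr(plv_list[[1L]], "times")
  if (is.null(times)) stop("no time axis supplied", call. = FALSE)
  electrodes <- rownames(plv_list[[1L]])
  np <- length(plv_list)
  for (p in plv_list) {
    stopifnot(identical(rownames(p), electrodes),
              ncol(p) == length(times))
  }
  t_idx <- seq(1L, length(times), by = as.integer(time_stride))
  with_seed(seed, {
    base_mean <- matrix(NA_real_, np, length(electrodes),
                        dimnames = list(NULL, electrodes))
    for (i in seq_len(np)) {
      for (ch in electrodes) {
        base_mean[i, ch] <- bootstrap_baseline_mean(
          plv_list[[i]][ch, ], times, baseline_window, n_boot, seed = NULL)
      }
    }
    pmat <- matrix(NA_real_, length(electrodes), length(t_idx),
                   dimnames = list(electrodes, NULL))
    for (ch in electrodes) {
      vals <- vapply(plv_list, function(p) p[ch, t_idx],
                     numeric(length(t_idx)))   # times x participants
      for (j in seq_along(t_idx)) {
        smp <- vals[j, ]
        res <- if (direction == "greater") {
          bootstrap_paired_test(smp, base_mean[, ch], n_boot, seed = NULL)
        } else {
          bootstrap_paired_test(base_mean[, ch], smp, n_boot, seed = NULL)
        }
        pmat[ch, j] <- res$p_value
      }
    }
    structure(list(significant = pmat <= alpha, p = pmat,
                   times = times[t_idx], baseline_mean = base_mean,
                   alpha = alpha, n_boot = n_boot, seed = seed,
                   direction = direction),
              class = "eplv_mask")
  })
}

#' @export
print.eplv_mask <- function(x, ...) {
  cat("<eplv_mask> ", nrow(x$significant), " electrodes x ",
      ncol(x$significant), " time points, alpha=", x$alpha, ", ",
      sum(x$significant), " significant cells\n", sep = "")
  invisible(x)
}

#' Connection counts over time
#'
#' @param mask an `eplv_mask`.
#' @return list with `counts` (data frame time, n_connections), `peak_time`
#'   (earliest time of the maximum count) and `peak_count`.
#' @export
connection_summary <- function(mask) {
  stopifnot(inherits(mask, "eplv_mask"))
  counts <- colSums(mask$significant)
  peak <- which.max(counts)   # earliest index on ties
  list(counts = data.frame(time = mask$times, n_connections = counts),
       peak_time = mask$times[peak], peak_count = counts[peak])
}
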
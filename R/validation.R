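#' Simulated multi-participant ePLV detection study
#'
#' End-to-end validation experiment: for each simulated participant, a
#' recording with occipital-seeded band-limited coupling to known target
#' electrodes is generated, band-filtered, epoched, and reduced to
#' occipital-seeded PLV series; the group is then screened with
#' [screen_eplv] and scored against the generator's ground truth.
#'
#' Sensitivity is the fraction of injected (electrode, time) cells flagged
#' within the coupling window; the false-positive rate is the fraction of
#' post-stimulus cells flagged on electrodes that received no coupling.
#'
#' @param n_participants simulated participants.
#' @param n_trials trials (epochs) per participant.
#' @param targets electrodes receiving the coupled oscillation.
#' @param band_center coupling frequency, Hz.
#' @param kappa von Mises concentration of the per-trial phase jitter.
#' @param window coupling window, seconds post-onset.
#' @param band analysis band c(low, high), Hz.
#' @param alpha screening level.
#' @param n_boot bootstrap replicates.
#' @param time_stride screen every n-th sample.
#' @param seed integer seed.
#' @return list with `mask` (the [screen_eplv] result), `sensitivity`,
#'   `false_positive_rate`, `targets`, `n_participants`.
#' @export
simulate_eplv_study <- function(n_participants = 19, n_trials = 40,
                                targets = c("C3", "C4", "P4"),
                                band_center = 5.5, kappa = 4,
                                window = c(0.15, 0.40), band = c(4, 7),
                                alpha = 0.05, n_boot = 1000,
                                time_stride = 10, seed = 1L) {
  montage <- generate_montage("paper64")
  plv_list <- lapply(seq_len(n_participants), function(i) {
    cfg <- synth_config(
      montage = montage, n_trials_per_condition = n_trials,
      conditions = "A", blink_rate = 0, outlier_trial_fraction = 0,
      coupling_specs = list(coupling_spec(targets, band_center,
                                          concentration = kappa,
                                          window = window)),
      seed = seed + 1000L * i)
    rec <- bandpass_zero_phase(generate_recording(cfg), band[1], band[2])
    occipital_plv(extract_epochs(rec), montage)
  })
  times <- attr(plv_list[[1L]], "times")
  mask <- screen_eplv(plv_list, times = times, alpha = alpha,
                      n_boot = n_boot, seed = seed + 999983L,
                      time_stride = time_stride)
  tin <- mask$times >= window[1] & mask$times <= window[2]
  post <- mask$times > 0
  others <- setdiff(rownames(mask$significant), targets)
  list(mask = mask,
       sensitivity = mean(mask$significant[targets, tin]),
       false_positive_rate = mean(mask$significant[others, post]),
       targets = targets, n_participants = n_participants)
}
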
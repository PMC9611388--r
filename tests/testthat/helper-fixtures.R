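# Shared fixtures, built in code at test time.

demo_m <- generate_montage("demo21")
full_m <- generate_montage("paper64")

# Small clean generator configuration (no artifacts) on the 21-channel
# montage; pass extra synth_config arguments through `...`.
quick_cfg <- function(..., seed = 1L) {
  args <- utils::modifyList(
    list(montage = demo_m, n_trials_per_condition = 5,
         conditions = c("A", "D"), blink_rate = 0,
         outlier_trial_fraction = 0, seed = seed),
    list(...))
  do.call(synth_config, args)
}

# Epochs built directly from a per-epoch signal generator, bypassing the
# synth module: fn(epoch_index) must return a channels x time matrix.
make_epochs <- function(fn, n_epochs = 4, channels = c("c1", "c2"),
                        srate = 500, tmin = -0.2, tmax = 1.0,
                        conditions = NULL) {
  times <- seq(round(tmin * srate), round(tmax * srate)) / srate
  data <- array(0, c(n_epochs, length(channels), length(times)),
                dimnames = list(NULL, channels, NULL))
  for (e in seq_len(n_epochs)) data[e, , ] <- fn(e)
  eeg_epochs(data, times, srate,
             conditions %||% rep("A", n_epochs))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
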
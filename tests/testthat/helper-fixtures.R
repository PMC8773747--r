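# Shared fixtures: all built in code, no stored data.

noiseless_params <- function(amplitude = 1) {
  sim_params(response_amplitude = amplitude, drift_amp = 0, mayer_amp = 0,
             resp_amp = 0, cardiac_amp = 0, white_sd = 0)
}

# One participant with an exact right-hemisphere gain (no jitter).
participant_with_gain <- function(gain) {
  list(id = "p01", right_gain = gain)
}

# Simulate -> band-pass (dHbO) -> epoch -> baseline-correct one recording.
preprocessed_epochs <- function(schedule, gain, params = noiseless_params(),
                                seed = 0L, chromophores = "hbo") {
  ts <- simulate_hemodynamics(schedule, participant_with_gain(gain), params,
                              seed = seed)
  tf <- bandpass(ts, chromophores = chromophores)
  baseline_correct(epoch(tf, trial_onsets(schedule)))
}

# Build an epoch_table entry as consumed by lis_by_group_session().
epoch_entry <- function(group, session, epochs, id = "p01") {
  list(id = id, group = group, session = session, epochs = epochs)
}

# Hand-built epoch_set (trials x channels x samples) for unit tests that
# need exact sample values rather than a simulated recording.
manual_epoch_set <- function(hbo, fs = 8.138, n_pre = floor(fs),
                             baseline_corrected = FALSE) {
  n <- dim(hbo)[3]
  structure(list(
    hbo = hbo, hbr = -hbo / 3,
    t_rel = ((-n_pre):(n - n_pre - 1)) / fs,
    onset_index = n_pre + 1L,
    baseline_window = c(-n_pre / fs, 0),
    fs = fs,
    baseline_corrected = baseline_corrected
  ), class = "epoch_set")
}
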
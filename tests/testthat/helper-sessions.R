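# Shared fixtures, built once per test run and cached across files.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# 30-trial (10 per condition) default-physiology session.
small_session <- function() {
  cached("small_session",
         simulate_session(sim_config(n_trials_per_condition = 10L,
                                     seed = 42L)))
}

# Same session, average-referenced and epoched (no broadband FIR: the RESS
# stage band-limits on its own).
small_epochs <- function() {
  cached("small_epochs",
         epoch_recording(rereference_average(small_session()$recording)))
}

# Noise-free single-condition session for exact linear-mixing recovery.
clean_session <- function() {
  cached("clean_session",
         simulate_session(sim_config(
           n_trials_per_condition = 6L,
           conditions = c(control = 0.70),
           noise_rms = 1e-4, alpha_amplitude = 0, amplitude_jitter = 0,
           seed = 9L)))
}

# Small white-noise recording for preprocessing tests.
noise_recording <- function(n_channels = 8L, n_sec = 20L, sfreq = 250,
                            seed = 5L) {
  set.seed(seed)
  mont <- montage_1020(max(n_channels, 4L))
  eeg_recording(matrix(rnorm(n_channels * n_sec * sfreq),
                       nrow = n_channels),
                sfreq = sfreq,
                channel_labels = mont$label[seq_len(n_channels)],
                channel_positions = as.matrix(
                  mont[seq_len(n_channels), c("x", "y", "z")]))
}

# Single-trial epochs container around a channel x time matrix.
matrix_epochs <- function(data, sfreq, metadata = NULL) {
  eeg_epochs(array(data, dim = c(1L, nrow(data), ncol(data)),
                   dimnames = list(NULL, rownames(data), NULL)),
             sfreq = sfreq, metadata = metadata)
}
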
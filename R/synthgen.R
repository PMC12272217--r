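# Synthetic EEG session generator.
#
# Emulates a frequency-tagged spatial-attention session: two lateral flickers
# at 13 Hz (left hemifield) and 15 Hz (right hemifield) drive occipital
# SSVEP sources whose amplitude depends on the flicker modulation depth and
# on which side is attended; background activity is 1/f (pink) noise plus a
# posterior alpha rhythm that is partially suppressed once gaze/attention
# shifts at cue onset. Ground truth (attended side, condition, injected
# source amplitudes, mixing topographies) is returned alongside the
# recording so recovery can be tested exactly.

#' Standard 32-channel 10-20 montage with 3-D positions
#'
#' Spherical-head electrode positions (unit radius) for a standard 32-channel
#' extended 10-20 layout. Coordinates: +x right, +y anterior, +z superior.
#'
#' @param n_channels Number of channels (first `n_channels` of the layout;
#'   default all 32).
#' @return A data.frame with `label`, `x`, `y`, `z`.
#' @export
montage_1020 <- function(n_channels = 32L) {
  # (theta, phi) in the easycap convention: theta = inclination from the
  # vertex, signed negative for the left hemisphere; phi = azimuth.
  tab <- matrix(c(
    -90, -72,   90,  72,  -90, -36,  -60, -51,   45,  90,   60,  51,
     90,  36,  -69, -21,  -31, -46,   31,  46,   69,  21,  -90,   0,
    -45,   0,    0,   0,   45,   0,   90,   0, -113,  18,  -69,  21,
    -31,  46,   31, -46,   69, -21,  113, -18,  -90,  36,  -60,  51,
     45, -90,   60, -51,   90, -36, -113,  54,  -90,  72,   90, -90,
     90, -72,  113, -54), ncol = 2, byrow = TRUE)
  labels <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "FC5", "FC1",
              "FC2", "FC6", "T7", "C3", "Cz", "C4", "T8", "TP9", "CP5",
              "CP1", "CP2", "CP6", "TP10", "P7", "P3", "Pz", "P4", "P8",
              "PO9", "O1", "Oz", "O2", "PO10")
  if (n_channels < 4 || n_channels > length(labels))
    stop_invalid("n_channels must be in [4, ", length(labels), "]")
  th <- tab[, 1] * pi / 180
  ph <- tab[, 2] * pi / 180
  pos <- data.frame(label = labels,
                    x = sin(th) * cos(ph),
                    y = sin(th) * sin(ph),
                    z = cos(th))
  pos[seq_len(n_channels), ]
}

#' Generate 1/f ("pink") background noise
#'
#' Spectral-synthesis noise whose power spectral density follows
#' `f^(-exponent)`: independent Gaussian Fourier coefficients are shaped by
#' `f^(-exponent/2)` and transformed back to the time domain. The output is
#' zero-mean with unit RMS; scale it to the desired amplitude.
#'
#' @param n_samples Number of samples (> 1).
#' @param exponent Spectral slope; 0 gives white noise, 1 the classic 1/f
#'   EEG background.
#' @param sfreq Sampling rate in Hz.
#' @param seed Optional integer seed.
#' @return Numeric vector of length `n_samples`.
#' @export
make_pink_noise <- function(n_samples, exponent = 1, sfreq = 500,
                            seed = NULL) {
  if (!is.numeric(n_samples) || length(n_samples) != 1L || n_samples < 2)
    stop_invalid("n_samples must be a single integer > 1")
  check_number(exponent, "exponent", lower = 0)
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_samples)
  freqs <- seq_len(n %/% 2) * sfreq / n
  shape <- freqs^(-exponent / 2)
  # positive-frequency coefficients; Hermitian completion gives a real series
  coefs <- complex(real = rnorm(length(freqs)),
                   imaginary = rnorm(length(freqs))) * shape
  spec <- complex(length.out = n)
  spec[2:(n %/% 2 + 1L)] <- coefs
  if (n %% 2L == 0L)  # Nyquist bin must be real
    spec[n %/% 2 + 1L] <- complex(real = rnorm(1) * shape[length(shape)])
  spec[n - seq_len((n - 1L) %/% 2) + 1L] <-
    Conj(spec[1L + seq_len((n - 1L) %/% 2)])
  x <- Re(fft(spec, inverse = TRUE)) / n
  x <- x - mean(x)
  x / sd(x)
}

#' Effective contrast-response gain of a flicker
#'
#' Maps amplitude modulation depth to an effective neural response gain with
#' a compressive power law `depth^gamma`. The mapping is monotone, 0 at
#' depth 0 and 1 at depth 1.
#'
#' @param depth Modulation depth(s) in \[0, 1\] (vectorized).
#' @param gamma Power-law exponent (> 0); the default 0.5 is compressive,
#'   consistent with the modest SNR loss observed at strongly reduced
#'   contrast.
#' @return Numeric gain(s) in \[0, 1\].
#' @export
contrast_response <- function(depth, gamma = 0.5) {
  if (!is.numeric(depth) || any(!is.finite(depth)) ||
      any(depth < 0 | depth > 1))
    stop_invalid("depth must be numeric in [0, 1]")
  check_number(gamma, "gamma", lower = 0, allow_zero = FALSE)
  depth^gamma
}

#' Steady-state response source at a tag frequency
#'
#' Builds the source time course of an SSVEP generator: sinusoids at the
#' stimulation frequency and its first harmonic (2f), weighted by
#' `harmonic_weights` and multiplied by a time-varying amplitude envelope.
#' The response is modelled at f and 2f only — the two lines the analysis
#' characterizes — rather than as a full square-wave following response.
#'
#' @param freq Fundamental frequency in Hz.
#' @param envelope Amplitude envelope, one value per sample, in \[0, Inf).
#' @param harmonic_weights Length-2 weights for (f, 2f); default `c(1, 0.3)`.
#' @param sfreq Sampling rate in Hz.
#' @param phase Phase offset in radians at t = 0.
#' @return Numeric vector, `length(envelope)` samples; unit amplitude at the
#'   fundamental when the envelope is 1.
#' @export
make_ssvep_source <- function(freq, envelope, harmonic_weights = c(1, 0.3),
                              sfreq = 500, phase = 0) {
  check_number(freq, "freq", lower = 0, allow_zero = FALSE)
  if (length(harmonic_weights) != 2L)
    stop_invalid("harmonic_weights must have length 2 (f, 2f)")
  if (harmonic_weights[2] > 0 && 2 * freq >= sfreq / 2)
    stop_invalid("2f must be below Nyquist when the 2f weight is positive")
  n <- length(envelope)
  if (n == 0L) stop_invalid("envelope must be non-empty")
  t <- (seq_len(n) - 1L) / sfreq
  envelope * (harmonic_weights[1] * sin(2 * pi * freq * t + phase) +
              harmonic_weights[2] * sin(2 * pi * 2 * freq * t + 2 * phase))
}

#' Configuration of a synthetic frequency-tagging session
#'
#' Defaults mirror the experimental protocol the package models: 32 channels
#' at 500 Hz; 30 trials per modulation-depth condition (control 70%,
#' periliminal 2%, subliminal one ascending staircase step of 0.02
#' percentage points below); trials of 3 s fixation + 3 s cue + 3 s target;
#' tag frequencies 13 Hz (left hemifield) and 15 Hz (right).
#'
#' @param n_channels Channel count (10-20 montage subset), default 32.
#' @param sfreq Sampling rate in Hz, default 500.
#' @param n_trials_per_condition Trials per condition, default 30.
#' @param conditions Named numeric vector of modulation depths.
#' @param phase_durations Named seconds for fixation, cue, target.
#' @param tag_freqs Named Hz pair, left and right flicker frequencies.
#' @param ssvep_gain Source amplitude in microvolts per unit effective
#'   contrast gain (unattended baseline).
#' @param attention_ratio Attended/unattended source amplitude ratio (> 0;
#'   > 1 produces an attention effect).
#' @param amplitude_jitter SD of the log-normal trial-to-trial fluctuation
#'   of each source's amplitude (default 0.12). Real SSVEP amplitudes vary
#'   from trial to trial with arousal and attentional state; this is what
#'   keeps single-trial decoding of the high-contrast condition near, not
#'   at, ceiling. 0 disables it.
#' @param visibility_threshold Modulation depth below which the flicker is
#'   invisible to the simulated participant, so covert attention is never
#'   deployed to it and the attention_ratio does not apply. Default equals
#'   the periliminal depth.
#' @param onset_ramp Seconds of linear amplitude rise after cue onset,
#'   default 0.5 (attention takes effect in about half a second).
#' @param harmonic_weights Relative source amplitude at (f, 2f).
#' @param contrast_gamma Power-law exponent of [contrast_response()].
#' @param noise_exponent 1/f slope of the background noise.
#' @param noise_rms Per-channel background noise RMS in microvolts.
#' @param alpha_band Hz range of the posterior alpha rhythm.
#' @param alpha_amplitude Alpha source RMS in microvolts.
#' @param alpha_suppression Multiplicative alpha attenuation during the
#'   cue and target phases (gaze/attention shift), default 0.7.
#' @param inter_trial_interval Seconds between trials (no flicker), default 1.
#' @param seed Integer seed used by [simulate_session()].
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_channels = 32L, sfreq = 500,
                       n_trials_per_condition = 30L,
                       conditions = c(control = 0.70, periliminal = 0.02,
                                      subliminal = 0.0198),
                       phase_durations = c(fixation = 3, cue = 3, target = 3),
                       tag_freqs = c(left = 13, right = 15),
                       ssvep_gain = 1.5, attention_ratio = 1.5,
                       amplitude_jitter = 0.12,
                       visibility_threshold = 0.02, onset_ramp = 0.5,
                       harmonic_weights = c(1, 0.3), contrast_gamma = 0.5,
                       noise_exponent = 1, noise_rms = 2.5,
                       alpha_band = c(8, 12), alpha_amplitude = 1.5,
                       alpha_suppression = 0.7, inter_trial_interval = 1,
                       seed = 1L) {
  check_number(sfreq, "sfreq", lower = 0, allow_zero = FALSE)
  if (any(phase_durations <= 0)) stop_invalid("all durations must be > 0")
  if (length(tag_freqs) != 2L || tag_freqs[1] == tag_freqs[2])
    stop_invalid("tag_freqs must be two distinct frequencies")
  if (any(tag_freqs >= sfreq / 2))
    stop_invalid("tag frequencies must be below sfreq/2")
  if (any(conditions < 0 | conditions > 1))
    stop_invalid("modulation depths must be in [0, 1]")
  check_number(attention_ratio, "attention_ratio", lower = 0,
               allow_zero = FALSE)
  check_number(amplitude_jitter, "amplitude_jitter", lower = 0)
  check_number(onset_ramp, "onset_ramp", lower = 0)
  check_number(noise_exponent, "noise_exponent", lower = 0)
  check_number(inter_trial_interval, "inter_trial_interval", lower = 0)
  if (is.null(names(conditions)))
    names(conditions) <- paste0("cond", seq_along(conditions))
  structure(
    list(n_channels = as.integer(n_channels), sfreq = sfreq,
         n_trials_per_condition = as.integer(n_trials_per_condition),
         conditions = conditions, phase_durations = phase_durations,
         tag_freqs = tag_freqs, ssvep_gain = ssvep_gain,
         attention_ratio = attention_ratio,
         amplitude_jitter = amplitude_jitter,
         visibility_threshold = visibility_threshold,
         onset_ramp = onset_ramp, harmonic_weights = harmonic_weights,
         contrast_gamma = contrast_gamma, noise_exponent = noise_exponent,
         noise_rms = noise_rms, alpha_band = alpha_band,
         alpha_amplitude = alpha_amplitude,
         alpha_suppression = alpha_suppression,
         inter_trial_interval = inter_trial_interval,
         seed = as.integer(seed)),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<sim_config> %d ch @ %g Hz, %d trials x %d conditions (depths: %s),\n",
    "  tags %g/%g Hz, gain %g uV, attention ratio %g, noise RMS %g uV, seed %d\n"),
    x$n_channels, x$sfreq, x$n_trials_per_condition, length(x$conditions),
    paste(signif(x$conditions, 3), collapse = "/"),
    x$tag_freqs[1], x$tag_freqs[2], x$ssvep_gain, x$attention_ratio,
    x$noise_rms, x$seed))
  invisible(x)
}

# Gaussian scalp weighting around a 3-D center on the unit sphere,
# normalized to a maximum of 1.
gaussian_topography <- function(positions, center, sigma = 0.5) {
  center <- center / sqrt(sum(center^2))
  d2 <- (positions$x - center[1])^2 + (positions$y - center[2])^2 +
    (positions$z - center[3])^2
  w <- exp(-d2 / (2 * sigma^2))
  w / max(w)
}

#' Simulate a full frequency-tagged attention session
#'
#' Generates a continuous multichannel recording with event markers plus
#' ground truth. Per trial: during fixation both tag sources are driven at
#' the unattended baseline amplitude (gaze at the center); from cue onset,
#' the attended-side source rises over `onset_ramp` seconds to
#' `attention_ratio` times baseline — provided the flicker's modulation
#' depth reaches the simulated visibility threshold — and stays there
#' through the target phase. Sources are mixed to the scalp through
#' parieto-occipital Gaussian topographies (contralateral to the attended
#' hemifield), then 1/f noise and a cue-suppressed alpha rhythm are added.
#'
#' @param config A [sim_config()].
#' @return An object of class `ssvep_session`: list with `recording` (an
#'   [eeg_recording()]), `ground_truth` (data.frame: trial, condition, depth,
#'   side, per-phase source amplitudes), `topographies` (channel x source
#'   matrix) and `config`.
#' @examples
#' sess <- simulate_session(sim_config(n_trials_per_condition = 2, seed = 7))
#' sess$recording
#' @export
simulate_session <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "simulate_session"))
  sf <- config$sfreq
  mont <- montage_1020(config$n_channels)
  nch <- nrow(mont)

  pd <- config$phase_durations
  trial_dur <- sum(pd)
  slot_dur <- trial_dur + config$inter_trial_interval
  n_cond <- length(config$conditions)
  n_trials <- config$n_trials_per_condition * n_cond
  lead_in <- 1  # seconds of plain background before the first trial
  n_total <- as.integer(round((lead_in + n_trials * slot_dur) * sf))

  # trial schedule: conditions blocked (as in the protocol), sides balanced
  # and randomly ordered within each block
  cond_seq <- rep(names(config$conditions),
                  each = config$n_trials_per_condition)
  side_seq <- unlist(lapply(seq_len(n_cond), function(i) {
    s <- rep(c("left", "right"), length.out = config$n_trials_per_condition)
    sample(s)
  }))
  onset <- as.integer(round((lead_in + (seq_len(n_trials) - 1) * slot_dur) *
                              sf)) + 1L

  depths <- config$conditions[cond_seq]
  gains <- contrast_response(unname(depths), config$contrast_gamma)
  base_amp <- config$ssvep_gain * gains
  visible <- unname(depths) >= config$visibility_threshold
  r_eff <- ifelse(visible, config$attention_ratio, 1)
  # trial-to-trial log-normal amplitude fluctuation, one factor per source
  # per trial (unit mean)
  jit <- matrix(exp(rnorm(2L * n_trials, 0, config$amplitude_jitter) -
                      config$amplitude_jitter^2 / 2), nrow = 2L)

  # per-source amplitude envelopes over the whole recording
  env <- matrix(0, nrow = 2, ncol = n_total)  # rows: left(13), right(15)
  tgt_of_side <- c(left = 1L, right = 2L)
  n_fix <- as.integer(round(pd[["fixation"]] * sf))
  n_cue <- as.integer(round(pd[["cue"]] * sf))
  n_tgt <- as.integer(round(pd[["target"]] * sf))
  n_ramp <- as.integer(round(config$onset_ramp * sf))
  for (i in seq_len(n_trials)) {
    idx <- onset[i]:(onset[i] + n_fix + n_cue + n_tgt - 1L)
    att <- tgt_of_side[[side_seq[i]]]
    una <- 3L - att
    # attended source ramps to r_eff x baseline from cue onset
    post <- (n_fix + 1L):length(idx)
    ramp <- if (n_ramp > 0)
      pmin(1, (seq_along(post) - 1L) / n_ramp) else 1
    amp_att <- rep(base_amp[i] * jit[att, i], length(idx))
    amp_att[post] <- base_amp[i] * jit[att, i] * (1 + (r_eff[i] - 1) * ramp)
    env[att, idx] <- env[att, idx] + amp_att
    env[una, idx] <- env[una, idx] + base_amp[i] * jit[una, i]
  }

  src13 <- make_ssvep_source(config$tag_freqs[["left"]], env[1L, ],
                             config$harmonic_weights, sf,
                             phase = runif(1, 0, 2 * pi))
  src15 <- make_ssvep_source(config$tag_freqs[["right"]], env[2L, ],
                             config$harmonic_weights, sf,
                             phase = runif(1, 0, 2 * pi))

  # alpha rhythm: narrowband noise, suppressed during cue+target
  alpha_c <- mean(config$alpha_band)
  alpha_fwhm <- diff(range(config$alpha_band))
  alpha <- gaussian_bandpass(rnorm(n_total), alpha_c, alpha_fwhm, sf)
  alpha <- alpha / sd(alpha)
  supp <- rep(1, n_total)
  for (i in seq_len(n_trials)) {
    idx <- (onset[i] + n_fix):(onset[i] + n_fix + n_cue + n_tgt - 1L)
    supp[idx] <- config$alpha_suppression
  }
  alpha <- alpha * supp * config$alpha_amplitude

  # mixing: contralateral parieto-occipital topographies
  topo <- cbind(
    src13 = gaussian_topography(mont, c(0.40, -0.85, -0.10), 0.5),
    src15 = gaussian_topography(mont, c(-0.40, -0.85, -0.10), 0.5),
    alpha = gaussian_topography(mont, c(0, -0.90, 0.44), 0.7))
  rownames(topo) <- mont$label

  data <- topo[, "src13"] %o% src13 + topo[, "src15"] %o% src15 +
    topo[, "alpha"] %o% alpha
  for (ch in seq_len(nch))
    data[ch, ] <- data[ch, ] +
      config$noise_rms * make_pink_noise(n_total, config$noise_exponent, sf)

  events <- data.frame(
    sample = as.integer(c(rbind(onset, onset + n_fix,
                                onset + n_fix + n_cue))),
    phase = rep(c("fixation", "cue", "target"), n_trials),
    side = rep(side_seq, each = 3L),
    condition = rep(cond_seq, each = 3L),
    trial = rep(seq_len(n_trials), each = 3L))

  rec <- eeg_recording(data, sfreq = sf, channel_labels = mont$label,
                       channel_positions = as.matrix(mont[, c("x", "y", "z")]),
                       events = events)

  att_i <- tgt_of_side[side_seq]
  jit_att <- jit[cbind(att_i, seq_len(n_trials))]
  jit_una <- jit[cbind(3L - att_i, seq_len(n_trials))]
  gt <- data.frame(
    trial = seq_len(n_trials), condition = cond_seq, depth = unname(depths),
    side = side_seq,
    amp_fixation_attended = base_amp * jit_att,
    amp_fixation_unattended = base_amp * jit_una,
    amp_task_attended = base_amp * jit_att * r_eff,
    amp_task_unattended = base_amp * jit_una,
    attended_freq = config$tag_freqs[side_seq],
    row.names = NULL)

  structure(list(recording = rec, ground_truth = gt, topographies = topo,
                 config = config),
            class = "ssvep_session")
}

#' @export
print.ssvep_session <- function(x, ...) {
  cat(sprintf(
    "<ssvep_session> %d trials (%s), %d channels @ %g Hz, %.0f s\n",
    nrow(x$ground_truth),
    paste(names(x$config$conditions), collapse = "/"),
    nrow(x$recording$data), x$config$sfreq,
    ncol(x$recording$data) / x$config$sfreq))
  invisible(x)
}

#' Write session ground truth to TSV
#'
#' @param session An [simulate_session()] result.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_ground_truth <- function(session, path) {
  stopifnot(inherits(session, "ssvep_session"))
  utils::write.table(session$ground_truth, path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
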
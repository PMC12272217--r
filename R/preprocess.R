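# Continuous-data conditioning and epoching.
#
# The conditioning chain is: zero-phase FIR band-pass -> statistical
# bad-channel detection -> spherical-spline interpolation -> average
# reference -> (optional component pruning) -> epoching. Each step records
# itself in the recording's history and refuses to run after a later-stage
# step, so the chain cannot be silently reordered; steps may be skipped.

.step_rank <- c(bandpass_filter = 1, spherical_interpolate = 2,
                rereference_average = 3, prune_components = 4, epoch = 5)

check_step_order <- function(rec, step) {
  done <- max(c(0, .step_rank[rec$history]), na.rm = TRUE)
  if (.step_rank[[step]] < done)
    stop_invalid(step, " cannot run after a later preprocessing stage (",
                 paste(rec$history, collapse = " -> "), ")")
}

#' Construct a continuous EEG recording
#'
#' @param data Channel x sample numeric matrix (microvolts).
#' @param sfreq Sampling rate in Hz.
#' @param channel_labels Unique channel names, one per row of `data`.
#' @param channel_positions Optional n x 3 matrix of electrode positions on
#'   the unit sphere (required for spherical interpolation).
#' @param events Optional data.frame with at least `sample` (1-based) and
#'   `phase` columns; `side`, `condition`, `trial` columns are carried along.
#' @param reference Reference description, `"none"`, a label, or
#'   `"average"`.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, sfreq, channel_labels = rownames(data),
                          channel_positions = NULL, events = NULL,
                          reference = "none") {
  data <- as.matrix(data)
  if (!is.numeric(data) || any(!is.finite(data)))
    stop_invalid("data must be a finite numeric matrix")
  check_number(sfreq, "sfreq", lower = 0, allow_zero = FALSE)
  if (is.null(channel_labels))
    channel_labels <- paste0("Ch", seq_len(nrow(data)))
  if (anyDuplicated(channel_labels))
    stop_invalid("channel labels must be unique")
  if (length(channel_labels) != nrow(data))
    stop_invalid("one label per data row required")
  rownames(data) <- channel_labels
  if (!is.null(events)) {
    if (!all(c("sample", "phase") %in% names(events)))
      stop_invalid("events need at least 'sample' and 'phase' columns")
    events <- events[order(events$sample), , drop = FALSE]
  }
  structure(list(data = data, sfreq = sfreq,
                 channel_positions = channel_positions, events = events,
                 reference = reference, n_interpolated = 0L,
                 n_pruned = 0L, history = character(0)),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), %d events, ref: %s\n",
    nrow(x$data), ncol(x$data), x$sfreq, ncol(x$data) / x$sfreq,
    if (is.null(x$events)) 0L else nrow(x$events), x$reference))
  if (length(x$history))
    cat("  history:", paste(x$history, collapse = " -> "), "\n")
  invisible(x)
}

#' Effective data rank after preprocessing
#'
#' Channels minus interpolated channels minus one if average-referenced;
#' downstream decompositions (ICA, GED) should not exceed it.
#'
#' @param rec An [eeg_recording()].
#' @return Integer rank.
#' @export
effective_rank <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  nrow(rec$data) - rec$n_interpolated -
    as.integer(identical(rec$reference, "average"))
}

# Single-pass linear-phase FIR with group-delay compensation (zero net
# phase). FFT convolution padded to a power of two; edges are left as
# filter roll-on.
apply_fir <- function(x, h) {
  n <- length(x)
  L <- length(h)
  N <- nextn(n + L - 1L, 2L)
  full <- Re(fft(fft(c(x, numeric(N - n))) * fft(c(h, numeric(N - L))),
                 inverse = TRUE)) / N
  delay <- (L - 1L) %/% 2L
  full[delay + seq_len(n)]
}

#' Zero-phase FIR band-pass filter
#'
#' Hamming windowed-sinc linear-phase FIR applied once with group-delay
#' compensation. With the default length of 1651 taps at 500 Hz, the
#' passband is 1-40 Hz with half-amplitude (-6 dB) points at 0.5 and
#' 40.5 Hz. At other sampling rates the length is rescaled proportionally.
#'
#' @param rec An [eeg_recording()].
#' @param l_freq,h_freq Lower/upper -6 dB cutoff frequencies in Hz
#'   (defaults 0.5 and 40.5).
#' @param n_taps Filter length in samples (odd; default 1651 at 500 Hz).
#' @return The filtered recording.
#' @export
bandpass_filter <- function(rec, l_freq = 0.5, h_freq = 40.5,
                            n_taps = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  check_step_order(rec, "bandpass_filter")
  if (is.null(n_taps)) n_taps <- round(1651 * rec$sfreq / 500)
  n_taps <- as.integer(n_taps)
  if (n_taps %% 2L == 0L) n_taps <- n_taps + 1L  # type-I (odd length)
  if (ncol(rec$data) <= n_taps)
    stop_invalid("recording shorter than the filter (", n_taps, " taps)")
  h <- fir_bandpass_taps(n_taps, l_freq, h_freq, rec$sfreq)
  for (ch in seq_len(nrow(rec$data)))
    rec$data[ch, ] <- apply_fir(rec$data[ch, ], h)
  rec$history <- c(rec$history, "bandpass_filter")
  rec
}

#' Band-pass FIR coefficients (Hamming windowed sinc)
#'
#' Difference of two Hamming-windowed sinc low-pass kernels. The windowed
#' sinc has its half-amplitude point at the cutoff, so the band-pass
#' response is at -6 dB at `l_freq` and `h_freq`. Exposed so the frequency
#' response can be inspected directly.
#'
#' @param n_taps Odd filter length.
#' @param l_freq,h_freq -6 dB cutoffs in Hz.
#' @param sfreq Sampling rate in Hz.
#' @return Numeric vector of `n_taps` coefficients.
#' @export
fir_bandpass_taps <- function(n_taps, l_freq, h_freq, sfreq) {
  if (h_freq >= sfreq / 2) stop_invalid("h_freq must be below Nyquist")
  if (l_freq >= h_freq) stop_invalid("l_freq must be below h_freq")
  lp <- function(fc) {
    k <- seq_len(n_taps) - 1L - (n_taps - 1L) / 2
    h <- ifelse(k == 0, 2 * fc / sfreq,
                sin(2 * pi * fc / sfreq * k) / (pi * k))
    w <- 0.54 - 0.46 * cos(2 * pi * (seq_len(n_taps) - 1L) / (n_taps - 1L))
    h * w
  }
  lp(h_freq) - lp(l_freq)
}

#' Detect statistically deviant channels
#'
#' Flags channels whose average log power spectral density (Welch, 1-40 Hz,
#' 2 s segments, 50% overlap) deviates by more than `threshold` robust
#' standard deviations (1.4826 x MAD) from the median across channels.
#'
#' @param rec An [eeg_recording()].
#' @param threshold Deviation threshold in robust SDs (default 3).
#' @param fmin,fmax Frequency band of the summary statistic.
#' @return Character vector of flagged channel labels (possibly empty).
#' @export
detect_bad_channels <- function(rec, threshold = 3, fmin = 1, fmax = 40) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (nrow(rec$data) < 4L) stop_invalid("need at least 4 channels")
  stat <- apply(rec$data, 1L, function(x) {
    w <- welch_psd(x, rec$sfreq)
    keep <- w$freq >= fmin & w$freq <= fmax
    mean(log10(pmax(w$psd[keep], .Machine$double.xmin)))
  })
  med <- median(stat)
  rsd <- stats::mad(stat)
  if (rsd == 0) return(character(0))
  rownames(rec$data)[abs(stat - med) > threshold * rsd]
}

# Spherical-spline interpolation matrix machinery (Perrin-style splines,
# order m, truncated Legendre series, ridge regularization).
legendre_sum <- function(x, m = 4L, n_terms = 7L) {
  # sum_{n=1..N} (2n+1) / (n(n+1))^m * P_n(x), elementwise over x
  p_prev <- rep(1, length(x))  # P_0
  p_cur <- x                   # P_1
  acc <- (2 * 1 + 1) / (1 * 2)^m * p_cur
  for (n in 2:n_terms) {
    p_next <- ((2 * n - 1) * x * p_cur - (n - 1) * p_prev) / n
    acc <- acc + (2 * n + 1) / (n * (n + 1))^m * p_next
    p_prev <- p_cur
    p_cur <- p_next
  }
  acc / (4 * pi)
}

spline_gram <- function(pos_a, pos_b, m = 4L, n_terms = 7L) {
  cosang <- tcrossprod(pos_a, pos_b)  # rows unit-normalized
  matrix(legendre_sum(pmin(pmax(cosang, -1), 1), m, n_terms),
         nrow = nrow(pos_a))
}

#' Spherical-spline interpolation of bad channels
#'
#' Replaces flagged channels with a spherical-spline estimate (order m = 4,
#' 7-term Legendre truncation, ridge regularization 1e-5) computed from the
#' remaining channels' signals and unit-sphere positions. Good channels are
#' untouched; the interpolation count is recorded for rank bookkeeping.
#'
#' @param rec An [eeg_recording()] with channel positions.
#' @param bad Character vector of channel labels to rebuild.
#' @param m Spline order (default 4).
#' @param n_terms Legendre series truncation (default 7).
#' @param lambda Ridge regularization (default 1e-5).
#' @return The recording with interpolated data and updated
#'   `n_interpolated`.
#' @export
spherical_interpolate <- function(rec, bad, m = 4L, n_terms = 7L,
                                  lambda = 1e-5) {
  stopifnot(inherits(rec, "eeg_recording"))
  check_step_order(rec, "spherical_interpolate")
  if (length(bad) == 0L) return(rec)
  labels <- rownames(rec$data)
  if (!all(bad %in% labels)) stop_invalid("unknown channel in 'bad'")
  if (is.null(rec$channel_positions))
    stop_invalid("channel positions required for spherical interpolation")
  good <- setdiff(labels, bad)
  if (length(good) < 4L) stop_invalid("fewer than 4 good channels remain")

  pos <- rec$channel_positions
  pos <- pos / sqrt(rowSums(pos^2))
  rownames(pos) <- labels
  G <- spline_gram(pos[good, , drop = FALSE], pos[good, , drop = FALSE],
                   m, n_terms)
  k <- length(good)
  A <- rbind(cbind(G + diag(lambda, k), rep(1, k)), c(rep(1, k), 0))
  rhs <- rbind(rec$data[good, , drop = FALSE], 0)
  sol <- solve(A, rhs)                     # spline coefficients + constant
  Gb <- spline_gram(pos[bad, , drop = FALSE], pos[good, , drop = FALSE],
                    m, n_terms)
  rec$data[bad, ] <- cbind(Gb, rep(1, length(bad))) %*% sol
  rec$n_interpolated <- rec$n_interpolated + length(bad)
  rec$history <- c(rec$history, "spherical_interpolate")
  rec
}

#' Re-reference to the channel average
#'
#' Subtracts the instantaneous mean across channels from every channel;
#' output column sums are zero and the data rank drops by one (recorded via
#' [effective_rank()]). Idempotent.
#'
#' @param rec An [eeg_recording()].
#' @return The re-referenced recording.
#' @export
rereference_average <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  check_step_order(rec, "rereference_average")
  if (nrow(rec$data) < 2L) stop_invalid("need at least 2 channels")
  rec$data <- sweep(rec$data, 2L, colMeans(rec$data))
  rec$reference <- "average"
  if (!"rereference_average" %in% rec$history)
    rec$history <- c(rec$history, "rereference_average")
  rec
}

#' Remove artifactual components by classification confidence
#'
#' Applies the confidence-based pruning rule to an existing linear
#' decomposition (e.g. ICA from any established implementation): components
#' whose classification confidence exceeds 0.70 (strictly) for any artifact
#' class — ocular, muscular, heart, line, electrode, other — are removed and
#' the data reconstructed from the remainder. The decomposition itself is an
#' input: this function owns only the pruning rule.
#'
#' @param rec An [eeg_recording()].
#' @param unmixing Component x channel unmixing matrix (square on the
#'   retained rank).
#' @param class_scores Component x class matrix of confidences; column
#'   names must cover the artifact classes present, e.g.
#'   `c("brain", "ocular", "muscular", "heart", "line", "electrode",
#'   "other")`. Rows must sum to at most 1 (+ small tolerance).
#' @param threshold Confidence above which a component is discarded
#'   (strict inequality; default 0.70).
#' @return The reconstructed recording with `n_pruned` updated.
#' @export
prune_components <- function(rec, unmixing, class_scores, threshold = 0.70) {
  stopifnot(inherits(rec, "eeg_recording"))
  check_step_order(rec, "prune_components")
  unmixing <- as.matrix(unmixing)
  class_scores <- as.matrix(class_scores)
  if (nrow(class_scores) != nrow(unmixing))
    stop_invalid("one score row per component required")
  if (any(rowSums(class_scores) > 1 + 1e-6))
    stop_invalid("class scores must sum to at most 1 per component")
  artifact <- intersect(colnames(class_scores),
                        c("ocular", "muscular", "heart", "line",
                          "electrode", "other"))
  if (length(artifact) == 0L)
    stop_invalid("no artifact-class columns found in class_scores")
  flagged <- apply(class_scores[, artifact, drop = FALSE] > threshold,
                   1L, any)
  if (all(flagged))
    stop_invalid("all components flagged as artifactual; refusing to ",
                 "reconstruct an empty decomposition")
  labs <- rownames(rec$data)
  mixing <- solve(unmixing)
  sources <- unmixing %*% rec$data
  rec$data <- mixing[, !flagged, drop = FALSE] %*%
    sources[!flagged, , drop = FALSE]
  rownames(rec$data) <- labs
  rec$n_pruned <- rec$n_pruned + sum(flagged)
  rec$history <- c(rec$history, "prune_components")
  rec
}

#' Epoch a recording around fixation onsets
#'
#' Cuts one `[0, 9]` s epoch per trial with the fixation onset at time 0
#' (fixation 0-3 s, cue 3-6 s, target 6-9 s by default). Trials whose epoch
#' would overrun the end of the recording are dropped with a warning.
#'
#' @param rec An [eeg_recording()] with events (phases fixation/cue/target).
#' @param tmin,tmax Epoch window in seconds relative to fixation onset.
#' @return An object of class `eeg_epochs`: `data` (trial x channel x time
#'   array), `times`, `sfreq`, `channel_labels`, `channel_positions`,
#'   `metadata` (trial, condition, side), `n_dropped`.
#' @export
epoch_recording <- function(rec, tmin = 0, tmax = 9) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (is.null(rec$events)) stop_invalid("recording has no events")
  fix <- rec$events[rec$events$phase == "fixation", , drop = FALSE]
  if (nrow(fix) == 0L) stop_invalid("no fixation events to epoch around")
  n_time <- as.integer(round((tmax - tmin) * rec$sfreq))
  start <- fix$sample + as.integer(round(tmin * rec$sfreq))
  ok <- start >= 1L & (start + n_time - 1L) <= ncol(rec$data)
  n_dropped <- sum(!ok)
  if (n_dropped > 0L)
    warning(n_dropped, " trial(s) dropped: epoch overruns the recording")
  if (!any(ok)) stop_invalid("zero complete trials after epoching")
  fix <- fix[ok, , drop = FALSE]
  start <- start[ok]
  n_trials <- length(start)
  nch <- nrow(rec$data)
  arr <- array(NA_real_, dim = c(n_trials, nch, n_time),
               dimnames = list(NULL, rownames(rec$data), NULL))
  for (i in seq_len(n_trials))
    arr[i, , ] <- rec$data[, start[i]:(start[i] + n_time - 1L)]
  meta <- data.frame(trial = fix$trial %||% seq_len(n_trials),
                     condition = fix$condition %||% NA_character_,
                     side = fix$side %||% NA_character_)
  structure(list(data = arr, sfreq = rec$sfreq,
                 times = tmin + (seq_len(n_time) - 1L) / rec$sfreq,
                 channel_labels = rownames(rec$data),
                 channel_positions = rec$channel_positions,
                 metadata = meta, n_dropped = n_dropped,
                 effective_rank = effective_rank(rec)),
            class = "eeg_epochs")
}

#' Construct an epochs container directly
#'
#' Usually produced by [epoch_recording()]; the direct constructor exists
#' for simulations and tests that build trial arrays themselves.
#'
#' @param data Trial x channel x time numeric array.
#' @param sfreq Sampling rate in Hz.
#' @param tmin Time of the first sample in seconds (default 0).
#' @param metadata Optional data.frame with one row per trial (`condition`,
#'   `side`, ...).
#' @param channel_labels Channel names (default from `dimnames`).
#' @param channel_positions Optional n x 3 electrode positions.
#' @return An object of class `eeg_epochs`.
#' @export
eeg_epochs <- function(data, sfreq, tmin = 0, metadata = NULL,
                       channel_labels = NULL, channel_positions = NULL) {
  if (length(dim(data)) != 3L)
    stop_invalid("data must be a trial x channel x time array")
  check_number(sfreq, "sfreq", lower = 0, allow_zero = FALSE)
  d <- dim(data)
  if (is.null(channel_labels))
    channel_labels <- dimnames(data)[[2]] %||% paste0("Ch", seq_len(d[2]))
  if (is.null(metadata))
    metadata <- data.frame(trial = seq_len(d[1]),
                           condition = NA_character_,
                           side = NA_character_)
  if (nrow(metadata) != d[1])
    stop_invalid("metadata must have one row per trial")
  structure(list(data = data, sfreq = sfreq,
                 times = tmin + (seq_len(d[3]) - 1L) / sfreq,
                 channel_labels = channel_labels,
                 channel_positions = channel_positions,
                 metadata = metadata, n_dropped = 0L,
                 effective_rank = d[2]),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<eeg_epochs> %d trials x %d channels x %d samples @ %g Hz, window [%g, %g] s\n",
    d[1], d[2], d[3], x$sfreq, min(x$times),
    max(x$times) + 1 / x$sfreq))
  if (!all(is.na(x$metadata$condition))) {
    tb <- table(x$metadata$condition, x$metadata$side)
    cat("  trials by condition x side:\n")
    print(tb)
  }
  invisible(x)
}
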
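# Internal helpers shared across modules.

# Consistent error signalling: all argument problems raise a condition that
# also carries class "freqtag_invalid" so callers/tests can distinguish
# contract violations from numerical failures.
stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("freqtag_invalid", "error")))
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_zero = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_invalid(name, " must be a single finite number")
  if (x < lower || x > upper)
    stop_invalid(name, " must be in [", lower, ", ", upper, "], got ", x)
  if (!allow_zero && x == 0) stop_invalid(name, " must be non-zero")
  invisible(x)
}

# Derive a reproducible child seed from a master seed and a stage label so
# that stages can be re-run in isolation. Kept below 2^31 - 1.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 2654435761 + h) %% .Machine$integer.max)
}

# Welch mean periodogram: average of modified periodograms over Hann-windowed
# segments with 50% overlap. Returns one-sided PSD in x-units^2/Hz so that
# sum(psd) * df equals the series variance (approximately, for long series).
welch_psd <- function(x, sfreq, seg_len = min(length(x), round(2 * sfreq)),
                      overlap = 0.5) {
  n <- length(x)
  if (seg_len < 8) stop_invalid("segment length too short for Welch PSD")
  step <- max(1L, floor(seg_len * (1 - overlap)))
  starts <- seq(1L, n - seg_len + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg_len) / (seg_len + 1))
  u <- sum(w^2)
  nf <- floor(seg_len / 2) + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1L)]
    seg <- (seg - mean(seg)) * w
    p <- abs(fft(seg))^2 / (u * sfreq)
    acc <- acc + p[seq_len(nf)]
  }
  psd <- acc / length(starts)
  # fold two-sided into one-sided (interior bins appear twice)
  if (nf > 2) psd[2:(nf - 1L)] <- 2 * psd[2:(nf - 1L)]
  list(freq = seq(0, by = sfreq / seg_len, length.out = nf), psd = psd)
}

# Slope of log10(psd) ~ log10(f) over [fmin, fmax]; used by tests and by
# bad-channel summaries.
psd_slope <- function(x, sfreq, fmin = 1, fmax = 40) {
  w <- welch_psd(x, sfreq)
  keep <- w$freq >= fmin & w$freq <= fmax & w$psd > 0
  unname(coef(stats::lm(log10(w$psd[keep]) ~ log10(w$freq[keep])))[2])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
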
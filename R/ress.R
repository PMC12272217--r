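# Rhythmic Entrainment Source Separation (RESS).
#
# A spatial filter that maximizes power at a stimulation frequency relative
# to its spectral neighborhood: channel covariance S of data narrow-band
# filtered at the target frequency (Gaussian, FWHM 1 Hz) is contrasted with
# the mean covariance R of data filtered at the two neighboring frequencies
# (+/- 1 Hz) through the generalized eigendecomposition S w = lambda R w.
# The eigenvector with the largest eigenvalue is the RESS component; applied
# to the channel data it yields a single time series with maximal SSVEP SNR.

#' Zero-phase Gaussian narrow-band filter
#'
#' Multiplies the signal's spectrum by a Gaussian amplitude response
#' centered on `f` with full width at half maximum `fwhm` (applied
#' symmetrically to negative frequencies), then transforms back. Zero phase
#' by construction.
#'
#' @param x Numeric vector (one time series).
#' @param f Center frequency in Hz.
#' @param fwhm Full width at half maximum of the amplitude response, Hz.
#' @param sfreq Sampling rate in Hz.
#' @return Filtered series, same length.
#' @export
gaussian_bandpass <- function(x, f, fwhm, sfreq) {
  check_number(f, "f", lower = 0, allow_zero = FALSE)
  check_number(fwhm, "fwhm", lower = 0, allow_zero = FALSE)
  if (f + fwhm >= sfreq / 2)
    stop_invalid("f + fwhm must be below Nyquist")
  n <- length(x)
  if (n / sfreq < 2 / fwhm)
    warning("series shorter than ", 2 / fwhm,
            " s: spectral resolution insufficient for fwhm = ", fwhm, " Hz")
  g <- gaussian_response(n, f, fwhm, sfreq)
  Re(fft(fft(x) * g, inverse = TRUE)) / n
}

# Gaussian amplitude response over the two-sided FFT frequency grid.
gaussian_response <- function(n, f, fwhm, sfreq) {
  freqs <- c(seq(0, by = sfreq / n, length.out = n %/% 2 + 1L),
             seq(-sfreq / n * ((n - 1L) %/% 2), by = sfreq / n,
                 length.out = (n - 1L) %/% 2))
  exp(-4 * log(2) * (abs(freqs) - f)^2 / fwhm^2)
}

# Filter all channels of one trial at several center frequencies sharing a
# single forward FFT per channel. data: channel x time. Returns a list of
# channel x time matrices, one per frequency.
multiband_filter <- function(data, freqs, fwhm, sfreq) {
  n <- ncol(data)
  fwd <- mvfft(t(data))
  lapply(freqs, function(f) {
    g <- gaussian_response(n, f, fwhm, sfreq)
    t(Re(mvfft(fwd * g, inverse = TRUE)) / n)
  })
}

#' Target and neighbor narrow-band covariance matrices
#'
#' For every trial, the epoch is Gaussian-filtered at the target frequency
#' `f` and at the two neighbor frequencies `f - d` and `f + d`; channel
#' covariances are computed on the fit window (by default cue onset to 6 s
#' after, i.e. the cue and target phases) and averaged over trials. `S` is
#' the target-band average, `R` the average of the two neighbor bands.
#'
#' @param epochs An [eeg_epochs()] object.
#' @param f Target frequency, Hz.
#' @param fwhm Target filter FWHM, Hz (default 1).
#' @param d Neighbor distance, Hz (default 1).
#' @param neighbor_fwhm Neighbor filter FWHM, Hz (default 1).
#' @param fit_window Seconds relative to cue onset (default `c(0, 6)`).
#' @param cue_onset Cue onset in epoch time, s (default 3).
#' @param trials Optional trial index subset.
#' @return List with matrices `S` and `R` (channel x channel).
#' @export
compute_covariances <- function(epochs, f, fwhm = 1, d = 1,
                                neighbor_fwhm = 1, fit_window = c(0, 6),
                                cue_onset = 3, trials = NULL) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  win <- cue_onset + fit_window
  sel <- which(epochs$times >= win[1] & epochs$times < win[2])
  if (length(sel) < 2L)
    stop_invalid("fit window not covered by the epochs")
  trials <- trials %||% seq_len(dim(epochs$data)[1])
  nch <- dim(epochs$data)[2]
  S <- matrix(0, nch, nch)
  R <- matrix(0, nch, nch)
  for (i in trials) {
    bands <- multiband_filter(epochs$data[i, , ], c(f, f - d, f + d),
                              fwhm, epochs$sfreq)
    # neighbor filters may have their own width
    if (neighbor_fwhm != fwhm)
      bands[2:3] <- multiband_filter(epochs$data[i, , ],
                                     c(f - d, f + d), neighbor_fwhm,
                                     epochs$sfreq)
    S <- S + stats::cov(t(bands[[1]][, sel]))
    R <- R + (stats::cov(t(bands[[2]][, sel])) +
                stats::cov(t(bands[[3]][, sel]))) / 2
  }
  S <- (S + t(S)) / (2 * length(trials))
  R <- (R + t(R)) / (2 * length(trials))
  dimnames(S) <- dimnames(R) <- list(epochs$channel_labels,
                                     epochs$channel_labels)
  list(S = S, R = R)
}

#' Fit a RESS spatial filter
#'
#' Solves the generalized eigendecomposition `S w = lambda R w` between the
#' target-band covariance `S` and the shrinkage-regularized neighbor-band
#' covariance `R` and keeps the eigenvector with the largest eigenvalue as
#' the RESS component. Weights are unit-norm with the sign fixed so the
#' component topography (`S w`) is positive at the posterior midline
#' channel.
#'
#' @param epochs An [eeg_epochs()] object, or `NULL` when `S`/`R` are given.
#' @param f Target frequency in Hz (stored; required when `epochs` given).
#' @param S,R Optional precomputed covariance pair (bypasses
#'   [compute_covariances()]).
#' @param shrinkage Fraction of the mean eigenvalue of `R` added to its
#'   diagonal (default 0.01); rank-deficient average-referenced data needs
#'   it.
#' @param ... Passed to [compute_covariances()] (`fwhm`, `d`,
#'   `neighbor_fwhm`, `fit_window`, `cue_onset`, `trials`).
#' @return An object of class `ress`: `weights`, `eigenvalues` (descending),
#'   `topography` (`S %*% weights`), `S`, `R`, `f`, `shrinkage`,
#'   `degenerate` flag, `channel_labels`.
#' @examples
#' co <- list(S = diag(c(4, 1)), R = diag(2))
#' f <- ress(S = co$S, R = co$R, f = 13)
#' coef(f)            # e1
#' f$eigenvalues[1]   # 4
#' @export
ress <- function(epochs = NULL, f = NULL, S = NULL, R = NULL,
                 shrinkage = 0.01, ...) {
  if (is.null(S) || is.null(R)) {
    stopifnot(inherits(epochs, "eeg_epochs"))
    check_number(f, "f", lower = 0, allow_zero = FALSE)
    co <- compute_covariances(epochs, f, ...)
    S <- co$S
    R <- co$R
  }
  S <- as.matrix(S)
  R <- as.matrix(R)
  if (!isTRUE(all.equal(dim(S), dim(R))) || nrow(S) != ncol(S))
    stop_invalid("S and R must be symmetric matrices of the same size")
  if (max(abs(S - t(S))) > 1e-8 * max(1, max(abs(S))) ||
      max(abs(R - t(R))) > 1e-8 * max(1, max(abs(R))))
    stop_invalid("S and R must be symmetric")
  check_number(shrinkage, "shrinkage", 0, 1)

  n <- nrow(S)
  mean_ev <- mean(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
  Rt <- (1 - shrinkage) * R + shrinkage * mean_ev * diag(n)
  L <- tryCatch(t(chol(Rt)), error = function(e) NULL)
  if (is.null(L))
    stop(errorCondition(
      "regularized R is numerically singular; increase shrinkage",
      class = c("freqtag_ged_failure", "error")))
  Linv <- forwardsolve(L, diag(n))
  M <- Linv %*% S %*% t(Linv)
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  W <- t(Linv) %*% e$vectors
  W <- sweep(W, 2L, sqrt(colSums(W^2)), "/")

  w <- W[, 1L]
  topo <- drop(S %*% w)
  labels <- rownames(S) %||%
    (if (!is.null(epochs)) epochs$channel_labels else
      paste0("Ch", seq_len(n)))
  pos <- if (!is.null(epochs)) epochs$channel_positions else NULL
  ref <- posterior_midline_index(labels, pos)
  if (topo[ref] < 0) {
    w <- -w
    topo <- -topo
    W[, 1L] <- w
  }
  lambdas <- e$values
  degenerate <- diff(range(lambdas)) < 1e-10 * max(1, abs(lambdas[1]))
  if (degenerate)
    warning("degenerate eigenvalue spectrum: no direction is preferred")

  structure(list(weights = w, eigenvalues = lambdas, all_weights = W,
                 topography = topo, S = S, R = R, f = f,
                 shrinkage = shrinkage, degenerate = degenerate,
                 channel_labels = labels),
            class = "ress")
}

# Channel whose topography sign anchors the component: posterior midline
# (most negative y, near-zero x) when positions are known, else the last
# channel.
posterior_midline_index <- function(labels, positions) {
  if (!is.null(positions))
    return(which.max(-positions[, 2] - 2 * abs(positions[, 1])))
  oz <- match("Oz", labels %||% character(0))
  if (!is.na(oz)) oz else length(labels %||% 1)
}

#' @export
print.ress <- function(x, ...) {
  cat(sprintf(
    "<ress> %s Hz component over %d channels, top eigenvalue %.3g%s\n",
    format(x$f %||% "?"), length(x$weights), x$eigenvalues[1],
    if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' @export
summary.ress <- function(object, ...) {
  cat(sprintf("RESS spatial filter at %s Hz\n", format(object$f %||% "?")))
  cat(sprintf("  channels: %d, shrinkage: %g\n", length(object$weights),
              object$shrinkage))
  cat(sprintf("  eigenvalues (top 5): %s\n",
              paste(signif(head(object$eigenvalues, 5), 4),
                    collapse = ", ")))
  top <- order(abs(object$topography), decreasing = TRUE)[1:3]
  cat(sprintf("  strongest topography channels: %s\n",
              paste(object$channel_labels[top], collapse = ", ")))
  invisible(object)
}

#' @export
coef.ress <- function(object, ...) {
  stats::setNames(object$weights, object$channel_labels)
}

#' Back-project a RESS filter onto epoched data
#'
#' Applies the spatial filter to every trial: `component(t) = w' data(t)`
#' over the full epoch window.
#'
#' @param object A fitted [ress()] filter.
#' @param epochs An [eeg_epochs()] with the same channel set.
#' @param ... Unused.
#' @return Trial x time matrix with a `times` attribute.
#' @export
predict.ress <- function(object, epochs, ...) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  d <- dim(epochs$data)
  if (d[2] != length(object$weights))
    stop_invalid("channel count mismatch between filter and epochs")
  out <- matrix(NA_real_, d[1], d[3])
  for (i in seq_len(d[1]))
    out[i, ] <- object$weights %*% epochs$data[i, , ]
  attr(out, "times") <- epochs$times
  attr(out, "sfreq") <- epochs$sfreq
  out
}

#' @export
plot.ress <- function(x, ...) {
  op <- par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  plot(x$eigenvalues, type = "b", xlab = "component",
       ylab = expression(lambda), main = "GED spectrum", ...)
  graphics::barplot(x$topography, names.arg = x$channel_labels,
                    las = 2, cex.names = 0.6, main = "topography (S w)")
  invisible(x)
}

#' SNR spectrum by neighbor-bin normalization
#'
#' Power at each frequency bin divided by the mean power of flanking bins
#' between `skip` and `span` Hz away on both sides. Featureless noise has
#' expectation about 1 everywhere; SSVEPs stand out as peaks at f and 2f.
#'
#' @param x Time series: vector, or trial x time matrix (as returned by
#'   [predict.ress()]); trials' power spectra are averaged before the ratio.
#' @param sfreq Sampling rate in Hz (taken from `x`'s attribute if present).
#' @param skip Half-width of the excluded gap around each bin, Hz
#'   (default 0.5).
#' @param span Outer reach of the neighborhood, Hz (default 2).
#' @return An object of class `snr_spectrum`: data.frame with `freq`, `snr`,
#'   and `power`.
#' @export
snr_spectrum <- function(x, sfreq = attr(x, "sfreq"), skip = 0.5,
                         span = 2) {
  if (is.null(sfreq)) stop_invalid("sfreq must be supplied")
  if (span <= skip) stop_invalid("span must exceed skip")
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  n <- ncol(x)
  if (n / sfreq < 2) stop_invalid("series must be at least 2 s long")
  sp <- mvfft(t(x * 1))
  pow <- rowMeans(abs(sp)^2)[seq_len(n %/% 2 + 1L)]
  freqs <- seq(0, by = sfreq / n, length.out = n %/% 2 + 1L)
  df <- sfreq / n
  k_skip <- max(1L, ceiling(skip / df))
  k_span <- floor(span / df)
  nb <- length(pow)
  snr <- rep(NA_real_, nb)
  offs <- c(-(k_span:k_skip), k_skip:k_span)
  for (i in seq_len(nb)) {
    neigh <- i + offs
    neigh <- neigh[neigh >= 1L & neigh <= nb]
    if (length(neigh)) snr[i] <- pow[i] / mean(pow[neigh])
  }
  structure(data.frame(freq = freqs, snr = snr, power = pow),
            class = c("snr_spectrum", "data.frame"),
            skip = skip, span = span)
}

#' @export
plot.snr_spectrum <- function(x, fmax = 40, ...) {
  keep <- x$freq <= fmax
  plot(x$freq[keep], x$snr[keep], type = "l", xlab = "frequency (Hz)",
       ylab = "SNR", ...)
  abline(h = 1, lty = 3)
  invisible(x)
}

#' Time-resolved SNR at a target frequency
#'
#' Slides a window along the component time series and evaluates the
#' neighbor-bin SNR at `f` in each window, per trial. The window must cover
#' at least two periods of the spectral resolution implied by the filters
#' (>= 2 s at 1 Hz FWHM).
#'
#' @param component Trial x time matrix from [predict.ress()] (or a vector).
#' @param f Target frequency in Hz.
#' @param sfreq Sampling rate (from attributes if present).
#' @param times Time stamps of the samples (from attributes if present).
#' @param window Window length, s (default 2).
#' @param step Window step, s (default 0.1).
#' @param skip,span Neighborhood parameters as in [snr_spectrum()].
#' @return An object of class `snr_timecourse`: list with `times` (window
#'   centers), `values` (trial x window matrix), `mean` trace, `f`,
#'   `normalized` flag.
#' @export
time_resolved_snr <- function(component, f, sfreq = attr(component, "sfreq"),
                              times = attr(component, "times"), window = 2,
                              step = 0.1, skip = 0.5, span = 2) {
  if (is.null(dim(component))) component <- matrix(component, nrow = 1L)
  if (is.null(sfreq)) stop_invalid("sfreq must be supplied")
  n <- ncol(component)
  if (is.null(times)) times <- (seq_len(n) - 1L) / sfreq
  nw <- as.integer(round(window * sfreq))
  if (nw > n) stop_invalid("window longer than the epoch")
  if (span <= skip) stop_invalid("span must exceed skip")
  starts <- seq(1L, n - nw + 1L, by = max(1L, as.integer(round(step * sfreq))))
  df <- sfreq / nw
  bin <- as.integer(round(f / df)) + 1L
  k_skip <- max(1L, ceiling(skip / df))
  k_span <- floor(span / df)
  neigh <- c(bin - (k_span:k_skip), bin + (k_skip:k_span))
  neigh <- neigh[neigh >= 1L & neigh <= nw %/% 2 + 1L]
  vals <- matrix(NA_real_, nrow(component), length(starts))
  for (j in seq_along(starts)) {
    seg <- component[, starts[j]:(starts[j] + nw - 1L), drop = FALSE]
    sp <- abs(mvfft(t(seg)))^2
    vals[, j] <- sp[bin, ] / colMeans(matrix(sp[neigh, ], ncol = ncol(sp)))
  }
  structure(list(times = times[starts] + window / 2,
                 values = vals, mean = colMeans(vals), f = f,
                 normalized = FALSE, window = window, step = step),
            class = "snr_timecourse")
}

#' @export
print.snr_timecourse <- function(x, ...) {
  cat(sprintf(
    "<snr_timecourse> %s%g Hz, %d trials x %d windows (%g s window, %g s step)\n",
    if (x$normalized) "normalized, " else "", x$f, nrow(x$values),
    ncol(x$values), x$window, x$step))
  invisible(x)
}

#' @export
plot.snr_timecourse <- function(x, ...) {
  plot(x$times, x$mean, type = "l", xlab = "time (s)",
       ylab = if (x$normalized) "SNR (target - nontarget)" else "SNR", ...)
  abline(h = if (x$normalized) 0 else 1, lty = 3)
  invisible(x)
}

#' Attention-normalized SSVEP time course
#'
#' The RESS filter maximizes SNR at its own frequency and therefore
#' overfits; the attentional effect is isolated by referencing the target
#' component against the nontarget one. Two conventions are provided:
#' `mode = "signal"` (default) subtracts the nontarget component time
#' series from the target component time series trial-by-trial before
#' computing the time-resolved SNR at the target frequency;
#' `mode = "snr"` computes each component's own SNR trace (at its own
#' frequency) and subtracts the nontarget trace from the target trace.
#'
#' @param epochs An [eeg_epochs()] object.
#' @param filt_target [ress()] filter at the attended frequency.
#' @param filt_nontarget [ress()] filter at the unattended frequency.
#' @param mode `"signal"` or `"snr"`.
#' @param ... Passed to [time_resolved_snr()].
#' @return An `snr_timecourse` with `normalized = TRUE`. Note normalized
#'   traces may be negative.
#' @export
normalize_attention <- function(epochs, filt_target, filt_nontarget,
                                mode = c("signal", "snr"), ...) {
  mode <- match.arg(mode)
  ct <- predict(filt_target, epochs)
  cn <- predict(filt_nontarget, epochs)
  if (mode == "signal") {
    diffc <- ct - cn
    attributes(diffc) <- attributes(ct)
    out <- time_resolved_snr(diffc, filt_target$f, ...)
  } else {
    st <- time_resolved_snr(ct, filt_target$f, ...)
    sn <- time_resolved_snr(cn, filt_nontarget$f, ...)
    out <- st
    out$values <- st$values - sn$values
    out$mean <- colMeans(out$values)
  }
  out$normalized <- TRUE
  out
}

#' Serialize a RESS filter to JSON
#'
#' @param object A [ress()] filter.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_ress <- function(object, path) {
  stopifnot(inherits(object, "ress"))
  jsonlite::write_json(
    list(f = object$f, shrinkage = object$shrinkage,
         channel_labels = object$channel_labels,
         weights = object$weights, eigenvalues = object$eigenvalues,
         topography = object$topography),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a serialized RESS filter
#'
#' @param path JSON path written by [write_ress()].
#' @return A `ress` object (without the covariance pair).
#' @export
read_ress <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(weights = j$weights, eigenvalues = j$eigenvalues,
                 topography = j$topography, S = NULL, R = NULL, f = j$f,
                 shrinkage = j$shrinkage, degenerate = FALSE,
                 channel_labels = j$channel_labels),
            class = "ress")
}
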
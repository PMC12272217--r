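test_that("gaussian bandpass has unit gain at centre and half at FWHM edges", {
  sf <- 500
  t <- seq(0, 20, by = 1 / sf)[-1]
  amp <- function(f_sig, f_filt, fwhm = 1) {
    y <- gaussian_bandpass(sin(2 * pi * f_sig * t), f_filt, fwhm, sf)
    sqrt(2) * sd(y[seq(5 * sf, 15 * sf)])
  }
  expect_equal(amp(13, 13), 1, tolerance = 0.01)
  expect_equal(amp(13.5, 13), 0.5, tolerance = 0.02)
  expect_equal(amp(12.5, 13), 0.5, tolerance = 0.02)
  expect_warning(gaussian_bandpass(rnorm(500), 13, 1, sf), "resolution")
  expect_error(gaussian_bandpass(rnorm(5000), 240, 20, sf),
               class = "freqtag_invalid")
})

test_that("gaussian bandpass confines white noise to the target band", {
  set.seed(6)
  sf <- 500
  y <- gaussian_bandpass(rnorm(2^15), 13, 1, sf)
  w <- freqtag:::welch_psd(y, sf, seg_len = 2^12)
  inband <- w$freq >= 13 - 2 & w$freq <= 13 + 2
  expect_gt(sum(w$psd[inband]) / sum(w$psd), 0.95)
})

test_that("covariance estimation isolates the target band", {
  ep <- small_epochs()
  # averaging identity: two copies of the same trial
  ep2 <- subset_epochs(ep, c(1L, 1L))
  co2 <- compute_covariances(ep2, 13)
  co1 <- compute_covariances(subset_epochs(ep, 1L), 13)
  expect_equal(co2$S, co1$S)
  expect_true(isSymmetric(co2$S) && isSymmetric(co2$R))

  # a pure f sinusoid on one channel dominates S's diagonal
  sf <- 250
  set.seed(7)
  n <- 10 * sf
  dat <- matrix(rnorm(6 * n, sd = 0.1), 6)
  dat[4, ] <- dat[4, ] + sin(2 * pi * 13 * (1:n) / sf)
  epx <- matrix_epochs(dat, sf)
  cox <- compute_covariances(epx, 13, fit_window = c(0, 6), cue_onset = 1)
  expect_equal(unname(which.max(diag(cox$S))), 4L)

  # with no target energy, S and R estimate the same (noise) covariance
  arr0 <- array(rnorm(10 * 6 * n), dim = c(10, 6, n))
  co0 <- compute_covariances(eeg_epochs(arr0, sf), 13,
                             fit_window = c(0, 6), cue_onset = 1)
  rel <- norm(co0$S - co0$R, "F") / norm(co0$R, "F")
  expect_lt(rel, 0.35)
})

test_that("generalized eigendecomposition solves the closed-form cases", {
  # identity case: flat spectrum, flagged degenerate
  expect_warning(f0 <- ress(S = diag(3), R = diag(3), f = 13),
                 "degenerate")
  expect_true(f0$degenerate)
  expect_equal(f0$eigenvalues, rep(1, 3))
  # diagonal case
  f1 <- ress(S = diag(c(4, 1)), R = diag(2), f = 13)
  expect_equal(f1$eigenvalues[1], 4, tolerance = 0.02)
  expect_equal(abs(f1$weights), c(1, 0), tolerance = 1e-6)
  # eigenvalues strictly descending
  expect_true(all(diff(f1$eigenvalues) <= 0))
  expect_error(ress(S = diag(2), R = matrix(c(1, 2, 0, 1), 2), f = 13),
               class = "freqtag_invalid")
})

test_that("the RESS component beats every single channel (GED optimality)", {
  sf <- 250
  n <- 12 * sf
  t <- (1:n) / sf
  snr_at <- function(x, f) {
    sp <- snr_spectrum(x, sfreq = sf)
    sp$snr[which.min(abs(sp$freq - f))]
  }
  set.seed(8)
  worse <- 0L
  for (rep in 1:20) {
    a <- rnorm(6)
    src <- 0.7 * sin(2 * pi * 13 * t + runif(1, 0, 2 * pi))
    dat <- a %o% src + matrix(rnorm(6 * n), 6)
    epx <- matrix_epochs(dat, sf)
    filt <- ress(epx, f = 13, fit_window = c(0, 10), cue_onset = 1)
    comp <- drop(predict(filt, epx))
    best_chan <- max(vapply(1:6, function(c) snr_at(dat[c, ], 13),
                            numeric(1)))
    if (snr_at(comp, 13) < best_chan) worse <- worse + 1L
  }
  expect_equal(worse, 0L)
})

test_that("eigenvalue exceeds 1 when target power exceeds the neighbours", {
  ep <- small_epochs()
  idx <- which(ep$metadata$condition == "control")
  filt <- ress(ep, f = 13, trials = idx)
  expect_gt(filt$eigenvalues[1], 1)
  expect_true(all(diff(filt$eigenvalues) <= 1e-12))
  # unit-norm weights, sign anchored at the posterior midline
  expect_equal(sum(coef(filt)^2), 1)
  expect_gt(filt$topography[which(ep$channel_labels == "Oz")], 0)
})

test_that("back-projection is the plain linear filter", {
  ep <- subset_epochs(small_epochs(), 1:4)
  filt <- structure(list(weights = c(1, numeric(31)), f = 13,
                         channel_labels = ep$channel_labels),
                    class = "ress")
  comp <- predict(filt, ep)
  expect_equal(comp[2, ], ep$data[2, 1, ])
  # linearity
  ep2 <- ep
  ep2$data <- ep2$data * 2
  expect_equal(predict(filt, ep2), comp * 2)
  # channel mismatch
  filt$weights <- c(1, 0)
  expect_error(predict(filt, ep), class = "freqtag_invalid")
})

test_that("SNR spectra are calibrated: noise at 1, tones scale with power", {
  set.seed(9)
  sf <- 250
  # featureless noise: mean SNR about 1 over 5-30 Hz
  x <- matrix(rnorm(20 * 8 * sf), nrow = 20)
  sp <- snr_spectrum(x, sfreq = sf)
  band <- sp$freq >= 5 & sp$freq <= 30
  expect_gt(mean(sp$snr[band]), 0.8)
  expect_lt(mean(sp$snr[band]), 1.25)
  # scale invariance
  sp2 <- snr_spectrum(x * 7.3, sfreq = sf)
  expect_equal(sp2$snr, sp$snr)
  # tone SNR grows with the square of its amplitude
  t <- (1:(8 * sf)) / sf
  noise <- matrix(rnorm(20 * 8 * sf), nrow = 20)
  snr13 <- function(a) {
    xx <- noise + rep(a * sin(2 * pi * 13 * t), each = 20)
    s <- snr_spectrum(xx, sfreq = sf)
    s$snr[which.min(abs(s$freq - 13))]
  }
  r <- snr13(2) / snr13(1)
  expect_gt(r, 3.2)
  expect_lt(r, 4.8)
  # off-target frequency of a pure tone stays at the noise floor
  tone <- matrix(sin(2 * pi * 13 * t), nrow = 1) +
    0.05 * matrix(rnorm(8 * sf), nrow = 1)
  s15 <- snr_spectrum(tone, sfreq = sf)
  expect_lt(s15$snr[which.min(abs(s15$freq - 15))], 2)
  expect_error(snr_spectrum(x, sfreq = sf, skip = 2, span = 1),
               class = "freqtag_invalid")
})

test_that("time-resolved SNR is flat for stationary signals", {
  set.seed(10)
  sf <- 250
  t <- (1:(9 * sf)) / sf
  x <- matrix(rep(sin(2 * pi * 13 * t), 10), nrow = 10, byrow = TRUE) +
    0.5 * matrix(rnorm(10 * 9 * sf), 10)
  tc <- time_resolved_snr(x, 13, sfreq = sf)
  expect_lt(sd(tc$mean) / mean(tc$mean), 0.2)
  # noise-only input hovers at 1
  tc0 <- time_resolved_snr(matrix(rnorm(10 * 9 * sf), 10), 13, sfreq = sf)
  expect_lt(abs(mean(tc0$mean) - 1), 0.3)
  expect_error(time_resolved_snr(x[, 1:300, drop = FALSE], 13, sfreq = sf,
                                 window = 2),
               class = "freqtag_invalid")
})

test_that("the attended component rises within a second of cue onset", {
  sess <- small_session()
  ep <- small_epochs()
  gt <- sess$ground_truth
  idx <- which(gt$condition == "control" & gt$side == "left")
  filt <- ress(ep, f = 13, trials = which(gt$condition == "control"))
  comp <- predict(filt, subset_epochs(ep, idx))
  tc <- time_resolved_snr(comp, 13)
  plateau <- mean(tc$mean[tc$times >= 4.5 & tc$times <= 8])
  base <- mean(tc$mean[tc$times <= 2.5])
  half <- base + 0.5 * (plateau - base)
  cross <- min(tc$times[tc$times > 2.5 & tc$mean >= half])
  # cue onset at 3 s; window-centre stamps of the 2-s window quantize the
  # crossing upward, so allow one step beyond 1 s
  expect_lte(cross, 4.1)
})

test_that("attention normalization cancels symmetric and self components", {
  ep <- small_epochs()
  gt <- small_session()$ground_truth
  ctrl <- which(gt$condition == "control")
  f13 <- ress(ep, f = 13, trials = ctrl)
  f15 <- ress(ep, f = 15, trials = ctrl)
  # self-subtraction: identical filters give an identically zero signal
  c13 <- predict(f13, ep)
  expect_equal(max(abs(c13 - c13)), 0)
  # left-attended control trials: positive normalized response during cue,
  # near zero during fixation
  left <- which(gt$condition == "control" & gt$side == "left")
  tcs <- normalize_attention(subset_epochs(ep, left), f13, f15,
                             mode = "snr")
  expect_true(tcs$normalized)
  fix_mean <- mean(tcs$mean[tcs$times <= 2.5])
  cue_mean <- mean(tcs$mean[tcs$times >= 4 & tcs$times <= 6])
  expect_gt(cue_mean, fix_mean)
  expect_gt(cue_mean, 0)
  # signal-mode subtraction also shows the cue-phase rise
  tsig <- normalize_attention(subset_epochs(ep, left), f13, f15,
                              mode = "signal")
  expect_gt(mean(tsig$mean[tsig$times >= 4 & tsig$times <= 6]),
            mean(tsig$mean[tsig$times <= 2.5]))
})

test_that("RESS filters serialize to JSON and back", {
  ep <- small_epochs()
  filt <- ress(ep, f = 15, trials = 1:10)
  path <- withr::local_tempfile(fileext = ".json")
  write_ress(filt, path)
  back <- read_ress(path)
  expect_equal(back$weights, filt$weights)
  expect_equal(back$f, 15)
  expect_equal(back$eigenvalues, filt$eigenvalues)
  # round-tripped filter still back-projects identically
  expect_equal(predict(back, subset_epochs(ep, 1:2)),
               predict(filt, subset_epochs(ep, 1:2)))
})
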
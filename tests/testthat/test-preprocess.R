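test_that("FIR band-pass preserves the passband and kills DC", {
  sf <- 500
  t <- seq(0, 30, by = 1 / sf)[-1]
  rec <- eeg_recording(rbind(sin(2 * pi * 20 * t), 5 + 0 * t),
                       sfreq = sf, channel_labels = c("sine", "dc"))
  out <- bandpass_filter(rec)
  mid <- seq(5 * sf, 25 * sf)  # away from edge roll-on
  # 20 Hz amplitude preserved within 1%
  expect_equal(sqrt(2) * sd(out$data["sine", mid]), 1, tolerance = 0.01)
  # zero net phase: filtered sine aligned with the original
  expect_gt(cor(out$data["sine", mid], sin(2 * pi * 20 * t)[mid]), 0.999)
  # DC is in the stopband (the 0-1 Hz transition leaves <1% of a 5 uV
  # offset)
  expect_lt(abs(mean(out$data["dc", mid])), 0.05)
  expect_error(bandpass_filter(eeg_recording(matrix(rnorm(200), 2),
                                             sfreq = sf)),
               class = "freqtag_invalid")
})

test_that("FIR -6 dB points sit at 0.5 and 40.5 Hz", {
  sf <- 500
  h <- fir_bandpass_taps(1651, 0.5, 40.5, sf)
  nfft <- 2^18
  H <- abs(fft(c(h, numeric(nfft - length(h)))))
  gain_db <- function(f) 20 * log10(H[round(f * nfft / sf) + 1])
  expect_lt(abs(gain_db(0.5) - (-6)), 0.5)
  expect_lt(abs(gain_db(40.5) - (-6)), 0.5)
  expect_lt(abs(gain_db(20)), 0.1)   # passband centre flat
  expect_lt(gain_db(60), -40)        # stopband
})

test_that("bad-channel detection flags only genuinely deviant channels", {
  rec <- noise_recording(8)
  expect_identical(detect_bad_channels(rec), character(0))
  # 20x broadband noise
  rec_bad <- rec
  rec_bad$data[3, ] <- rec_bad$data[3, ] * 20
  expect_identical(detect_bad_channels(rec_bad),
                   rownames(rec$data)[3])
  # flat channel deviates low
  rec_flat <- rec
  rec_flat$data[5, ] <- 0
  expect_identical(detect_bad_channels(rec_flat),
                   rownames(rec$data)[5])
})

test_that("spherical interpolation reproduces constants and smooth fields", {
  mont <- montage_1020(32)
  pos <- as.matrix(mont[, c("x", "y", "z")])
  set.seed(2)
  tc <- rnorm(200)
  # identity on empty bad set
  rec0 <- eeg_recording(matrix(rnorm(32 * 200), 32), sfreq = 100,
                        channel_labels = mont$label,
                        channel_positions = pos)
  expect_identical(spherical_interpolate(rec0, character(0))$data,
                   rec0$data)
  # constant scalp pattern is reproduced on the rebuilt channel
  rec1 <- eeg_recording(matrix(rep(tc, each = 32), 32), sfreq = 100,
                        channel_labels = mont$label,
                        channel_positions = pos)
  out1 <- spherical_interpolate(rec1, "Oz")
  expect_equal(out1$data["Oz", ], tc, tolerance = 0.01)
  expect_equal(out1$n_interpolated, 1L)
  # good channels untouched
  expect_identical(out1$data["Cz", ], rec1$data["Cz", ])
})

test_that("a dipolar field is recovered at a held-out electrode", {
  mont <- montage_1020(32)
  pos <- as.matrix(mont[, c("x", "y", "z")])
  set.seed(3)
  tc <- rnorm(300)
  pattern <- -pos[, 2] + 0.4 * pos[, 3]        # posterior-positive dipole
  data <- pattern %o% tc + 0.01 * matrix(rnorm(32 * 300), 32)
  rec <- eeg_recording(data, sfreq = 100, channel_labels = mont$label,
                       channel_positions = pos)
  truth <- rec$data["Oz", ]
  out <- spherical_interpolate(rec, "Oz")
  expect_gt(cor(out$data["Oz", ], truth), 0.9)
})

test_that("average reference zeroes the channel mean and is idempotent", {
  rec <- eeg_recording(matrix(c(1, 3), nrow = 2, ncol = 5), sfreq = 10)
  out <- rereference_average(rec)
  expect_equal(unname(out$data[, 1]), c(-1, 1))
  expect_equal(max(abs(colSums(out$data))), 0, tolerance = 1e-12)
  expect_equal(rereference_average(out)$data, out$data)
  expect_equal(out$reference, "average")
  expect_equal(effective_rank(out), 1L)
})

test_that("component pruning removes exactly the flagged subspace", {
  set.seed(4)
  n <- 2000
  S <- matrix(rnorm(4 * n), 4) * c(3, 2, 1.5, 1)
  A <- qr.Q(qr(matrix(rnorm(16), 4)))       # orthogonal mixing
  rec <- eeg_recording(A %*% S, sfreq = 100)
  scores <- matrix(0, 4, 2,
                   dimnames = list(NULL, c("brain", "ocular")))
  # nothing above threshold: reconstruction is exact
  scores[, "brain"] <- 1
  out0 <- prune_components(rec, unmixing = t(A), class_scores = scores)
  expect_equal(out0$data, rec$data, tolerance = 1e-10)
  # exactly at threshold: retained (strict inequality)
  scores2 <- scores
  scores2[2, ] <- c(0.30, 0.70)
  out_edge <- prune_components(rec, t(A), scores2)
  expect_equal(out_edge$n_pruned, 0L)
  # one ocular component above threshold: its variance is removed
  scores3 <- scores
  scores3[2, ] <- c(0.1, 0.9)
  out1 <- prune_components(rec, t(A), scores3)
  expect_equal(out1$n_pruned, 1L)
  v_expected <- sum(apply(S[-2, ], 1, var))
  expect_equal(sum(apply(t(A) %*% out1$data, 1, var)), v_expected,
               tolerance = 1e-8)
  # refusing to drop everything
  scores4 <- scores
  scores4[, "ocular"] <- 0.95
  scores4[, "brain"] <- 0
  expect_error(prune_components(rec, t(A), scores4),
               class = "freqtag_invalid")
})

test_that("epoching yields one 9-s epoch per complete trial", {
  sess <- small_session()
  ep <- small_epochs()
  expect_equal(dim(ep$data)[1], nrow(sess$ground_truth))
  expect_equal(dim(ep$data)[3], 9 * 500)
  expect_equal(ep$n_dropped, 0L)
  # rank ledger: 32 channels, average reference
  expect_equal(ep$effective_rank, 31L)
})

test_that("trials overrunning the recording are dropped with a warning", {
  sess <- simulate_session(sim_config(n_trials_per_condition = 3L,
                                      conditions = c(control = 0.7),
                                      seed = 21))
  rec <- sess$recording
  last_fix <- max(rec$events$sample[rec$events$phase == "fixation"])
  rec$data <- rec$data[, seq_len(last_fix + 500L)]  # 1 s after last onset
  expect_warning(ep <- epoch_recording(rec), "dropped")
  expect_equal(dim(ep$data)[1], 2L)
  expect_equal(ep$n_dropped, 1L)
  # a recording with no usable trial refuses
  rec2 <- rec
  rec2$data <- rec$data[, seq_len(400)]
  expect_error(suppressWarnings(epoch_recording(rec2)))
})

test_that("the conditioning chain cannot be reordered", {
  rec <- noise_recording(8, n_sec = 30, sfreq = 250)
  rec <- rereference_average(rec)
  expect_error(bandpass_filter(rec), class = "freqtag_invalid")
  rec2 <- noise_recording(8, n_sec = 30, sfreq = 250)
  rec2 <- rereference_average(rec2)
  expect_error(spherical_interpolate(rec2, "Fp1"),
               class = "freqtag_invalid")
})
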
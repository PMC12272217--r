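test_that("pink noise follows the requested spectral slope", {
  # white-noise limit
  x0 <- make_pink_noise(2^14, exponent = 0, sfreq = 500, seed = 1)
  expect_lt(abs(freqtag:::psd_slope(x0, 500)), 0.2)
  # 1/f: fitted log-log slope near -1 over 1-40 Hz
  x1 <- make_pink_noise(2^16, exponent = 1, sfreq = 500, seed = 2)
  sl <- freqtag:::psd_slope(x1, 500)
  expect_gte(sl, -1.2)
  expect_lte(sl, -0.8)
  # normalization
  expect_lt(abs(mean(x1)), 1e-10)
  expect_equal(sd(x1), 1)
})

test_that("pink noise is deterministic under a fixed seed", {
  expect_identical(make_pink_noise(4096, 1, 500, seed = 7),
                   make_pink_noise(4096, 1, 500, seed = 7))
  expect_error(make_pink_noise(0, 1, 500), class = "freqtag_invalid")
})

test_that("ssvep source concentrates power at f and 2f", {
  sf <- 500
  env <- rep(1, sf * 4)
  s <- make_ssvep_source(13, env, c(1, 0.3), sf)
  pow <- abs(fft(s))^2
  bins <- function(f) round(f * length(s) / sf) + 1
  expect_equal(pow[bins(26)] / pow[bins(13)], 0.09, tolerance = 1e-6)
  # spectral peaks only at f and 2f
  other <- pow[seq_len(length(s) %/% 2)][-c(bins(13), bins(26))]
  expect_lt(max(other) / pow[bins(13)], 1e-10)
  # zero envelope -> zero output
  expect_equal(make_ssvep_source(13, numeric(100), c(1, 0.3), sf),
               numeric(100))
  # zero envelope before onset -> exactly zero signal there
  env2 <- c(numeric(sf), seq(0, 1, length.out = sf))
  s2 <- make_ssvep_source(13, env2, c(1, 0.3), sf)
  expect_equal(s2[seq_len(sf)], numeric(sf))
  expect_gt(sd(s2[-seq_len(sf)]), 0)
})

test_that("ssvep source rejects aliasing harmonics", {
  expect_error(make_ssvep_source(70, rep(1, 100), c(1, 0.3), sfreq = 250),
               class = "freqtag_invalid")
  # no 2f content allowed when its weight is zero
  expect_silent(make_ssvep_source(70, rep(1, 100), c(1, 0), sfreq = 250))
})

test_that("contrast response is a monotone power law through (0,0), (1,1)", {
  expect_equal(contrast_response(0), 0)
  expect_equal(contrast_response(1, gamma = 1), 1)
  expect_equal(contrast_response(1), 1)
  expect_gt(contrast_response(0.04, 0.5), contrast_response(0.02, 0.5))
  d <- seq(0, 1, 0.05)
  expect_true(all(diff(contrast_response(d)) >= 0))
  expect_error(contrast_response(-0.1), class = "freqtag_invalid")
  expect_error(contrast_response(1.1), class = "freqtag_invalid")
})

test_that("default session has the protocol's trial and event structure", {
  sess <- cached("default_session",
                 simulate_session(sim_config(seed = 1)))
  expect_equal(nrow(sess$ground_truth), 90)
  expect_equal(nrow(sess$recording$events), 3 * 90)
  expect_equal(as.vector(table(sess$ground_truth$condition)),
               c(30, 30, 30))
  # sides balanced within condition
  expect_true(all(table(sess$ground_truth$condition,
                        sess$ground_truth$side) == 15))
  ep <- epoch_recording(sess$recording)
  expect_equal(dim(ep$data), c(90, 32, 9 * 500))
})

test_that("simulation is bit-identical under a fixed config", {
  cfg <- sim_config(n_trials_per_condition = 2L, seed = 33)
  a <- simulate_session(cfg)
  b <- simulate_session(cfg)
  expect_identical(a$recording$data, b$recording$data)
  expect_identical(a$ground_truth, b$ground_truth)
})

test_that("zero gain leaves tag frequencies at the noise floor", {
  sess <- simulate_session(sim_config(
    n_trials_per_condition = 12L, conditions = c(control = 0.7),
    ssvep_gain = 0, alpha_amplitude = 0, seed = 5))
  ep <- epoch_recording(sess$recording)
  oz <- which(ep$channel_labels == "Oz")
  # pool the per-phase segments of every trial before the spectral ratio
  segs <- do.call(rbind, lapply(c(0, 3, 6), function(t0) {
    ep$data[, oz, ep$times >= t0 & ep$times < t0 + 3]
  }))
  sp <- snr_spectrum(segs, sfreq = ep$sfreq)
  at <- function(f) sp$snr[which.min(abs(sp$freq - f))]
  expect_lt(abs(at(13) - 1), 0.5)
  expect_lt(abs(at(15) - 1), 0.5)
})

test_that("injected amplitudes are recovered from the noise-free mixture", {
  sess <- clean_session()
  ep <- epoch_recording(sess$recording)
  gt <- sess$ground_truth
  topo <- sess$topographies
  oz <- which(ep$channel_labels == "Oz")
  # target window: attended amplitude fully ramped, whole cycles of 13 Hz
  sel <- ep$times >= 6 & ep$times < 9
  n <- sum(sel)
  for (i in which(gt$side == "left")) {
    x <- ep$data[i, oz, sel]
    amp13 <- 2 * abs(fft(x)[round(13 * 3) + 1]) / n
    expected <- topo["Oz", "src13"] * gt$amp_task_attended[i]
    expect_lt(abs(amp13 - expected) / expected, 0.1)
  }
})

test_that("attended/unattended source power ratio equals the square of the attention ratio", {
  sess <- clean_session()
  r <- sess$config$attention_ratio
  ep <- epoch_recording(sess$recording)
  gt <- sess$ground_truth
  oz <- which(ep$channel_labels == "Oz")
  topo <- sess$topographies
  sel <- ep$times >= 6 & ep$times < 9
  n <- sum(sel)
  amp_at <- function(i, f) {
    2 * abs(fft(ep$data[i, oz, sel])[round(f * 3) + 1]) / n
  }
  ratios <- vapply(seq_len(nrow(gt)), function(i) {
    att <- if (gt$side[i] == "left") 13 else 15
    una <- if (gt$side[i] == "left") 15 else 13
    t_att <- if (att == 13) topo["Oz", "src13"] else topo["Oz", "src15"]
    t_una <- if (una == 13) topo["Oz", "src13"] else topo["Oz", "src15"]
    (amp_at(i, att) / t_att)^2 / (amp_at(i, una) / t_una)^2
  }, numeric(1))
  expect_equal(mean(ratios), r^2, tolerance = 0.1)
})

test_that("attention raises occipital SNR during cue relative to fixation", {
  sess <- small_session()
  ep <- epoch_recording(sess$recording)
  oz <- which(ep$channel_labels == "Oz")
  gt <- sess$ground_truth
  idx <- which(gt$condition == "control" & gt$side == "left")
  snr_in <- function(win) {
    sel <- ep$times >= win[1] & ep$times < win[2]
    sp <- snr_spectrum(ep$data[idx, oz, sel], sfreq = ep$sfreq)
    sp$snr[which.min(abs(sp$freq - 13))]
  }
  expect_gt(snr_in(c(3, 6)), snr_in(c(0, 3)))
})

test_that("ground truth is written as readable TSV", {
  sess <- small_session()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ground_truth(sess, path)
  tab <- read.delim(path)
  expect_equal(nrow(tab), nrow(sess$ground_truth))
  expect_true(all(c("trial", "condition", "side") %in% names(tab)))
})
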
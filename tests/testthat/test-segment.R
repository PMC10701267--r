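test_that("autocorrelation matches its closed form and brute force", {
  expect_equal(pcg_autocorr(rep(1, 4)), c(1, 0.75, 0.5, 0.25))
  expect_equal(pcg_autocorr(numeric(8)), numeric(8))
  set.seed(42)
  for (i in 1:5) {
    x <- rnorm(16)
    expect_equal(pcg_autocorr(x), oracle_autocorr(x), tolerance = 1e-12)
  }
  expect_error(pcg_autocorr(numeric(0)), "non-empty")
})

test_that("Hilbert envelope recovers amplitude and ignores sign", {
  fs_hz <- 2000; t <- (0:3999) / fs_hz
  x <- sin(2 * pi * 50 * t)
  env <- hilbert_envelope(x)
  core <- env[200:3800]
  expect_true(all(abs(core - 1) < 0.02))
  expect_equal(hilbert_envelope(-x), env)
  # Gaussian-windowed tone peaks at the window center
  g <- exp(-(t - 1)^2 / (2 * 0.03^2)) * sin(2 * pi * 60 * (t - 1))
  expect_lte(abs(which.max(hilbert_envelope(g)) - which.min(abs(t - 1))), 1)
})

test_that("cycle length is recovered from the envelope autocorrelation", {
  g <- gen_heart_sound(synth_spec(cycle_jitter_sd = 0, seed = 2))
  est <- estimate_cycle_length(g$record)
  expect_lt(abs(est - 1600) / 1600, 0.02)
  # strictly periodic pulse train: the estimate is the exact period
  fs_hz <- 2000; P <- 1000L
  t <- (0:(8 * fs_hz - 1)) / fs_hz
  x <- numeric(length(t))
  for (ctr in seq(0.25, 7.75, by = P / fs_hz)) {
    x <- x + exp(-(t - ctr)^2 / (2 * 0.02^2)) * sin(2 * pi * 60 * (t - ctr))
  }
  expect_identical(estimate_cycle_length(pcg_record(x, fs_hz)), P)
  set.seed(8)
  noise <- pcg_record(rnorm(8000) * 0.1, 2000)
  expect_error(estimate_cycle_length(noise), "cycle not found")
  expect_error(estimate_cycle_length(pcg_record(rnorm(1000), 2000)),
               "2 s")
})

test_that("ECG-guided labels agree with the generator ground truth", {
  for (seed in c(3, 29)) {
    g <- gen_heart_sound(synth_spec(seed = seed))
    sm <- label_from_ecg(g$record)
    truth <- truth_frames(g)
    expect_gte(mean(as.character(sm$states) == truth), 0.95)
    # boundaries tile the frame axis in cyclic order
    b <- sm$boundaries
    expect_identical(b$start_frame[-1], b$end_frame[-nrow(b)])
    expect_identical(b$start_frame[1], 0L)
  }
  one_r <- pcg_record(rnorm(4000), 2000, r_peaks = 100L, t_ends = 600L)
  expect_error(label_from_ecg(one_r), "complete R-R")
  no_fid <- pcg_record(rnorm(4000), 2000)
  expect_error(label_from_ecg(no_fid), "fiducials")
})

test_that("segment maps reject acyclic phase orders", {
  expect_error(segment_map(c("S1", "S2")), "cyclic order")
  expect_error(segment_map(c("S1", "systole", "S1")), "cyclic order")
  sm <- segment_map(c("diastole", "S1", "systole", "S2", "diastole", "S1"))
  expect_identical(nrow(sm$boundaries), 6L)
  expect_length(cycle_starts(sm), 1L)
})

test_that("duration model estimation recovers known dwell statistics", {
  # constant dwell: degenerate duration distribution
  states <- rep(rep(c("S1", "systole", "S2", "diastole"), 6),
                times = rep(c(20, 12, 20, 28), 6))
  sm <- segment_map(states, hop = 20L)
  feats <- rep(c(2, 0.1, 1.5, 0.1), 6)[rep(1:24, times =
    rep(c(20, 12, 20, 28), 6))] + stats::rnorm(length(states), 0, 0.01)
  m <- fit_dhmm(list(list(features = feats, segmap = sm)))
  expect_identical(unname(m$duration_mean["S1"]), 20)
  expect_identical(unname(m$duration_var["S1"]), 0)
  expect_identical(m$duration_pmf$S1$d, 20L)
  expect_identical(m$duration_pmf$S1$p, 1)
  for (st in pcg_states()) expect_equal(sum(m$duration_pmf[[st]]$p), 1)
  # Gaussian dwells: the recovered mean sits within two standard errors
  # of the generating mean
  set.seed(31)
  mu <- 22; sd_d <- 3; n_c <- 40
  dwell <- pmax(3, round(stats::rnorm(n_c, mu, sd_d)))
  states2 <- unlist(lapply(seq_len(n_c), function(i) {
    rep(c("S1", "systole", "S2", "diastole"), times = c(dwell[i], 10, 18, 25))
  }))
  sm2 <- segment_map(states2, hop = 20L)
  f2 <- stats::rnorm(length(states2))
  m2 <- fit_dhmm(list(list(features = f2, segmap = sm2)))
  expect_lt(abs(unname(m2$duration_mean["S1"]) - mu),
            2 * sd_d / sqrt(n_c - 1))
  expect_error(
    fit_dhmm(list(list(features = rnorm(40),
                       segmap = segment_map(rep("S1", 40))))),
    "absent")
})

test_that("decoded paths obey the cyclic transition structure", {
  model <- random_toy_dhmm(seed = 4)
  set.seed(4)
  obs <- rnorm(60)
  sm <- viterbi_segment(obs, model)
  codes <- as.integer(sm$states)
  steps <- cbind(codes[-length(codes)], codes[-1])
  changed <- steps[steps[, 1] != steps[, 2], , drop = FALSE]
  expect_true(all(changed[, 1] %% 4 + 1 == changed[, 2]))
})

test_that("short decodes match exhaustive enumeration", {
  for (seed in 1:8) {
    model <- random_toy_dhmm(seed = seed)
    set.seed(100 + seed)
    obs <- rnorm(16)
    got <- viterbi_segment(obs, model)
    ref <- oracle_hsmm_decode(obs, model)
    expect_equal(unname(attr(got, "log_score")), ref$score,
                 tolerance = 1e-9)
    expect_identical(as.integer(got$states), ref$states)
  }
})

test_that("segmentation is invariant to amplitude scaling", {
  g <- default_record()
  model <- fitted_dhmm()
  sm1 <- dhmm_segment(g$record, model)
  scaled <- pcg_record(g$record$samples * 0.2, g$record$sampling_rate)
  sm2 <- dhmm_segment(scaled, model)
  expect_identical(as.integer(sm1$states), as.integer(sm2$states))
})

test_that("the fitted model keeps the fixed transition structure", {
  m <- fitted_dhmm()
  expect_identical(unname(m$A), unname(dhmm_transition_matrix()))
  expect_identical(m$pi, rep(0.25, 4))
})

test_that("full-record decoding recovers the generated phases", {
  model <- fitted_dhmm()
  acc <- vapply(c(41, 52, 63), function(seed) {
    g <- gen_heart_sound(synth_spec(seed = seed))
    sm <- dhmm_segment(g$record, model)
    mean(as.character(sm$states) == truth_frames(g))
  }, numeric(1))
  expect_true(all(acc >= 0.9))
})

test_that("segment maps round-trip through CSV", {
  g <- default_record()
  sm <- label_from_ecg(g$record)
  path <- withr::local_tempfile(fileext = ".csv")
  write_segment_map(sm, path)
  back <- read_segment_map(path)
  expect_identical(as.integer(back$states), as.integer(sm$states))
})
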
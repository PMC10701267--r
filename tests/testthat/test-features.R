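test_that("power spectrum matches FFT identities and the naive DFT", {
  # DC frame of value 1, rectangular window: bin 0 carries L^2
  L <- 32L
  P <- power_spectrum(matrix(1, L, 1), fft_size = L)
  expect_equal(P[1, 1], L^2)
  # pure tone at a bin center concentrates in that bin
  k <- 4L
  tone <- sin(2 * pi * k * (0:(L - 1)) / L)
  Pt <- power_spectrum(matrix(tone, L, 1), fft_size = L)
  expect_identical(which.max(Pt[1, ]), k + 1L)
  expect_gt(Pt[1, k + 1] / sum(Pt[1, ]), 0.95)
  # random frames match the O(N^2) DFT oracle
  set.seed(7)
  for (i in 1:3) {
    fr <- rnorm(20)
    got <- power_spectrum(matrix(fr, 20, 1), fft_size = 32)
    ref <- oracle_dft_power(fr, 32)
    expect_equal(as.numeric(got), ref, tolerance = 1e-9)
  }
  expect_error(power_spectrum(matrix(1, 64, 1), fft_size = 32), ">=")
  expect_warning(power_spectrum(matrix(1, 10, 1), fft_size = 12),
                 "power of two")
})

test_that("Mel filters are unit-peak triangles that partition unity", {
  bank <- build_mel_bank(24, 512, 2000, 25, 1000)
  H <- bank$H
  ctr <- bank$centers_bin
  for (nf in seq_len(bank$n_filters)) {
    expect_equal(H[nf, ctr[nf] + 1], 1)
    left <- if (nf == 1) NULL else seq_len(ctr[nf - 1] + 1) - 1
  }
  # zero outside the triangle support
  expect_equal(H[5, seq_len(ctr[4])], rep(0, ctr[4]))
  K <- ncol(H)
  expect_equal(H[5, (ctr[6] + 2):K], rep(0, K - ctr[6] - 1))
  # adjacent filters sum to one between consecutive centers
  for (nf in 2:23) {
    ks <- (ctr[nf] + 1):(ctr[nf + 1])
    expect_equal(H[nf, ks + 1] + H[nf + 1, ks + 1], rep(1, length(ks)))
  }
  expect_error(build_mel_bank(200, 64, 2000, 25, 1000), "duplicate")
  expect_error(build_mel_bank(10, 512, 2000, 500, 400), "f_lo")
})

test_that("MFSC obeys its log-energy definition", {
  bank <- build_mel_bank(16, 256, 2000, 25, 1000)
  set.seed(21)
  fr <- matrix(rnorm(128 * 4), 128, 4)
  M <- mfsc(fr, bank)
  # independent per-filter dot-product oracle
  P <- power_spectrum(fr, bank$fft_size)
  for (i in 1:4) {
    expect_equal(as.numeric(M[i, ]), oracle_mfsc_frame(P[i, ], bank$H),
                 tolerance = 1e-9)
  }
  # scaling the signal by c adds exactly 2 log(c) to unfloored entries
  M2 <- mfsc(fr * 3, bank)
  expect_equal(M2, M + 2 * log(3), tolerance = 1e-9,
               ignore_attr = TRUE)
  # silent frames are floored, not -Inf
  M0 <- mfsc(matrix(0, 128, 2), bank)
  expect_true(all(is.finite(M0)))
  expect_equal(unique(as.numeric(M0)), log(1e-10))
})

test_that("homomorphic envelope tracks amplitude modulation", {
  fs_hz <- 2000; t <- (0:(6 * fs_hz - 1)) / fs_hz
  x <- 0.5 * sin(2 * pi * 80 * t)
  he <- homomorphic_envelope(x, fs_hz)
  expect_true(all(he > 0))
  core <- he[(0.5 * fs_hz):(5.5 * fs_hz)]
  expect_true(all(abs(core - 0.5) / 0.5 < 0.05))
  # 2 Hz modulator is recovered almost exactly
  mod <- 1 + 0.5 * sin(2 * pi * 2 * t)
  xm <- mod * sin(2 * pi * 80 * t)
  hem <- homomorphic_envelope(xm, fs_hz)
  sel <- (0.5 * fs_hz):(5.5 * fs_hz)
  expect_gte(stats::cor(hem[sel], mod[sel]), 0.98)
  expect_error(homomorphic_envelope(x, 500), "band-pass")
})

test_that("envelope pipeline is amplitude-equivariant", {
  g <- default_record()
  he1 <- homomorphic_envelope(g$record$samples, 2000)
  he2 <- homomorphic_envelope(g$record$samples * 4, 2000)
  expect_equal(he2, he1 * 4, tolerance = 1e-6)
})

test_that("vector max pooling follows the windowed maximum", {
  expect_equal(maxpool_vector(c(1, 5, 2, 4, 4, 4, 0, 0, 9), 3), c(5, 4, 9))
  x <- runif(100)
  pooled <- maxpool_vector(x, 7)
  expect_length(pooled, ceiling(100 / 7))
  expect_gte(min(pooled - vapply(seq_along(pooled), function(i) {
    max(x[((i - 1) * 7 + 1):min(i * 7, 100)])
  }, numeric(1))), 0)
})

test_that("envelope matrix is centralized and amplitude-normalized", {
  g <- default_record()
  sm <- label_from_ecg(g$record)
  env <- build_envelope_matrix(g$record, sm, pool_region = 3)
  expect_equal(mean(env$G), 0, tolerance = 1e-12)
  expect_equal(max(abs(env$G)), 1)
  expect_identical(nrow(env$G), length(cycle_starts(sm)))
  expect_error(build_envelope_matrix(g$record, sm, pool_region = 2),
               ">= 3")
  # pooled cycle length before row alignment is ceil(samples / region)
  cs <- cycle_starts(sm)
  lo <- cs[1] * sm$hop + 1; hi <- attr(cs, "ends")[1] * sm$hop
  pooled <- maxpool_vector(env$He[lo:hi], 3)
  expect_length(pooled, ceiling((hi - lo + 1) / 3))
  short <- segment_map(rep("S1", 50), hop = 20L)
  expect_error(build_envelope_matrix(g$record, short), "no cycle")
})
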
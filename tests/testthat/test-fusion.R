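test_that("a constant map never crosses its own mean-energy threshold", {
  M <- matrix(5, 200, 8)
  attr(M, "hop") <- 20; attr(M, "sampling_rate") <- 2000
  cycles <- cbind(start = c(0L, 80L), end = c(80L, 160L))
  mask <- detect_high_energy(M, cycles, window = 0.2)
  expect_false(any(mask))
})

test_that("two energy bumps per cycle produce two flagged runs", {
  n_fr <- 160
  energy <- rep(0, n_fr)
  # synthetic S1-like and S2-like bumps in two 80-frame cycles
  for (s in c(10, 50, 90, 130)) energy[s:(s + 14)] <- 3
  M <- matrix(energy, n_fr, 6)
  attr(M, "hop") <- 20; attr(M, "sampling_rate") <- 2000
  cycles <- cbind(start = c(0L, 80L), end = c(80L, 160L))
  mask <- detect_high_energy(M, cycles, window = 0.2)
  runs <- rle(mask)
  expect_identical(sum(runs$values), 4L)  # two runs in each of two cycles
  # flagged-run count is bounded by cycle length / window size
  expect_lte(sum(runs$values) / 2, ceiling(80 / 20))
  expect_error(detect_high_energy(M, cbind(start = 0L, end = 10L),
                                  window = 0.2), "longer than cycle")
  expect_error(detect_high_energy(M, cycles, window = 0), "> 0")
})

test_that("local overlay applies sum on the mask and mean elsewhere", {
  set.seed(12)
  M <- matrix(rnorm(64), 8, 8)
  G <- matrix(rnorm(64), 8, 8)
  mask <- rep(c(TRUE, FALSE), 4)
  W <- local_overlay(M, G, mask)
  expect_equal(unclass(W)[mask, ], (M + G)[mask, ], ignore_attr = TRUE)
  expect_equal(unclass(W)[!mask, ], ((M + G) / 2)[!mask, ],
               ignore_attr = TRUE)
  expect_equal(unclass(W), oracle_overlay(M, G, mask),
               tolerance = 1e-12, ignore_attr = TRUE)
  # M = G: masked doubles, unmasked passes through
  W2 <- local_overlay(M, M, mask)
  expect_equal(unclass(W2)[mask, ], 2 * M[mask, ], ignore_attr = TRUE)
  expect_equal(unclass(W2)[!mask, ], M[!mask, ], ignore_attr = TRUE)
  # G = 0: masked passes M, unmasked halves it
  W3 <- local_overlay(M, matrix(0, 8, 8), mask)
  expect_equal(unclass(W3)[mask, ], M[mask, ], ignore_attr = TRUE)
  expect_equal(unclass(W3)[!mask, ], M[!mask, ] / 2, ignore_attr = TRUE)
  expect_error(local_overlay(M, G[, 1:4], mask), "shape mismatch")
  expect_error(local_overlay(M, G, mask[1:3]), "mask length")
})

test_that("fusion is linear in its inputs for a fixed mask", {
  set.seed(3)
  M1 <- matrix(rnorm(40), 8, 5); M2 <- matrix(rnorm(40), 8, 5)
  G <- matrix(rnorm(40), 8, 5)
  mask <- c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, TRUE, FALSE)
  W12 <- local_overlay(M1 + M2, G * 2, mask)
  W1 <- local_overlay(M1, G, mask)
  W2 <- local_overlay(M2, G, mask)
  expect_equal(unclass(W12), unclass(W1) + unclass(W2),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("the high-energy gate captures the S1/S2 phases", {
  for (seed in c(3, 17)) {
    g <- gen_heart_sound(synth_spec(seed = seed))
    W <- extract_feature_map(g$record)
    mask <- attr(W, "high_energy_mask")
    truth <- truth_frames(g)
    idx <- seq_len(min(length(mask), length(truth)))
    capture <- mean(mask[idx][truth[idx] %in% c("S1", "S2")])
    expect_gte(capture, 0.8)
  }
})

test_that("re-gating a fused map keeps the original mask covered", {
  g <- default_record()
  W <- extract_feature_map(g$record)
  mask <- attr(W, "high_energy_mask")
  sm <- attr(W, "segmap")
  cs <- cycle_starts(sm)
  cycles <- cbind(start = as.integer(cs), end = as.integer(attr(cs, "ends")))
  mask2 <- detect_high_energy(W, cycles, window = 0.2,
                              hop = attr(W, "hop"),
                              sampling_rate = attr(W, "sampling_rate"))
  # energies only grew inside the mask, so flagged frames stay flagged
  expect_gte(mean(mask2[mask]), 0.95)
})

test_that("ablation modes pass a single map through", {
  g <- default_record()
  Wm <- extract_feature_map(g$record, mode = "mfsc-only")
  We <- extract_feature_map(g$record, mode = "envelope-only")
  Wo <- extract_feature_map(g$record, mode = "overlay")
  expect_identical(dim(Wm), dim(Wo))
  expect_identical(dim(We), dim(Wo))
  expect_false(isTRUE(all.equal(unclass(Wm), unclass(Wo))))
})

test_that("feature maps round-trip through TSV with metadata", {
  g <- default_record()
  W <- extract_feature_map(g$record)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_map(W, path)
  back <- read_feature_map(path)
  expect_equal(back, unclass(W), tolerance = 1e-10, ignore_attr = TRUE)
  expect_identical(attr(back, "high_energy_mask"),
                   attr(W, "high_energy_mask"))
})
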
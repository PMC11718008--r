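test_that("a single tone collapses into one dominant mode", {
  fs <- 20
  t <- (0:(120 * fs - 1)) / fs
  x <- sin(2 * pi * 1 * t)
  imfs <- vmd_decompose(x, fs)
  i <- which.max(imfs$powers)
  expect_equal(imfs$center_frequencies[i], 1, tolerance = 0.05)
  expect_gt(imfs$powers[i] / sum(imfs$powers), 0.95)
  expect_lt(sqrt(sum(imfs$residual^2) / sum(x^2)), 0.05)
})

test_that("two equal tones split power 50/50 at their frequencies", {
  fs <- 20
  t <- (0:(120 * fs - 1)) / fs
  x <- sin(2 * pi * 1 * t) + sin(2 * pi * 3 * t)
  imfs <- vmd_decompose(x, fs)
  top <- order(-imfs$powers)[1:2]
  expect_equal(sort(imfs$center_frequencies[top]), c(1, 3), tolerance = 0.05)
  split <- imfs$powers[top] / sum(imfs$powers[top])
  expect_equal(unname(split[1]), 0.5, tolerance = 0.05)
  expect_lt(sqrt(sum(imfs$residual^2) / sum(x^2)), 0.05)
})

test_that("zero input yields zero modes and residual", {
  imfs <- vmd_decompose(rep(0, 400), 20)
  expect_equal(max(abs(imfs$modes)), 0)
  expect_equal(max(abs(imfs$residual)), 0)
  expect_equal(ncol(imfs$modes), 10L)
})

test_that("modes are returned in ascending centre-frequency order", {
  fs <- 20
  t <- (0:(60 * fs - 1)) / fs
  x <- sin(2 * pi * 1.3 * t) + 0.5 * sin(2 * pi * 4.1 * t) + 0.2 * sin(2 * pi * 2.2 * t)
  imfs <- vmd_decompose(x, fs)
  expect_true(!is.unsorted(imfs$center_frequencies))
  expect_true(all(imfs$powers >= 0))
  expect_true(all(imfs$center_frequencies > 0 &
                    imfs$center_frequencies < fs))
})

test_that("decomposition matches the independent reference implementation", {
  # expected values computed by inst/reference/vmd_reference.py (an
  # independent transcription of the canonical alternating updates) on the
  # same LCG fixtures; centre frequencies within 0.05 Hz, power fractions
  # within 10%
  expected <- list(
    `101` = list(cf = c(1.0912, 2.5924, 4.2916),
                 frac = c(0.6060, 0.2971, 0.0970)),
    `102` = list(cf = c(1.0925, 2.5916, 4.2907),
                 frac = c(0.5941, 0.3078, 0.0981)),
    `103` = list(cf = c(1.0913, 2.5920, 4.2907),
                 frac = c(0.6046, 0.2990, 0.0964))
  )
  for (seed in c(101, 102, 103)) {
    fx <- vmd_reference_fixture(seed)
    imfs <- vmd_decompose(fx$x, fx$fs, alpha = 2000, merge_tol = 0.1,
                          reseed_rounds = 0)
    comp <- clustered_components(imfs, top = 3)
    ref <- expected[[as.character(seed)]]
    expect_equal(comp$cf, ref$cf, tolerance = 0.05)
    frac <- comp$power / sum(comp$power)
    expect_equal(frac, ref$frac, tolerance = 0.1)
  }
})

test_that("dominant-mode selection respects the exclusion list", {
  imfs <- structure(
    list(modes = matrix(0, 4, 3),
         center_frequencies = c(0.57, 0.95, 1.9),
         powers = c(5, 1, 0.5),
         residual = rep(0, 4), converged = TRUE, n_iter = 1L, fs = 20,
         band = c(0.8, 6)),
    class = "imf_set"
  )
  # unconstrained: plain argmax
  expect_equal(dominant_mode(imfs), 1L)
  # 0.57 is twice a 17/min breathing rate: runner-up wins
  excl <- (17 / 60) * (1:4)
  expect_equal(dominant_mode(imfs, excl), 2L)
  # everything excluded: no cardiac found
  expect_true(is.na(dominant_mode(imfs, c(0.57, 0.95, 1.9), tolerance = 0.01)))
})
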
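# pure set-to-zero-then-cumsum semantics (no dilation, zero fill)
plain_motion <- motion_config(fill = "zero", hysteresis = 0, spike_dilation = 0)

test_that("hand-traced step fixtures reproduce the zero-step semantics", {
  out <- compensate_movement(c(0, 0, 2, 2, 2), plain_motion)
  expect_equal(out$trace, c(0, 0, 0, 0, 0))
  expect_equal(out$spike_mask, c(FALSE, FALSE, TRUE, FALSE, FALSE))

  # same fixture through the pipeline defaults (dilation + interp): the
  # flat neighbourhood still yields all zeros
  out2 <- compensate_movement(c(0, 0, 2, 2, 2))
  expect_equal(out2$trace, c(0, 0, 0, 0, 0))

  # negative DC step is removed equally
  out3 <- compensate_movement(c(1, 1, -3, -3), plain_motion)
  expect_equal(out3$trace, c(1, 1, 1, 1))
})

test_that("sub-threshold traces pass through unchanged", {
  set.seed(11)
  for (i in 1:100) {
    x <- cumsum(runif(50, -0.4, 0.4))
    expect_identical(compensate_movement(x, plain_motion)$trace, x)
    expect_identical(compensate_movement(x)$trace, x)  # defaults too
  }
})

test_that("compensation is idempotent", {
  set.seed(12)
  for (i in 1:100) {
    x <- cumsum(runif(80, -0.3, 0.3))
    x[sample(10:70, 2)] <- x[sample(10:70, 2)] + runif(2, 2, 6)
    once <- compensate_movement(x, plain_motion)$trace
    twice <- compensate_movement(once, plain_motion)$trace
    expect_equal(twice, once)
    once_d <- compensate_movement(x)$trace
    twice_d <- compensate_movement(once_d)$trace
    expect_equal(twice_d, once_d)
  }
})

test_that("a narrow pulse artifact is removed to within 5% of clean", {
  prf <- 20
  t <- (0:(60 * prf - 1)) / prf
  clean <- sin(2 * pi * 0.25 * t)
  pulse <- numeric(length(t))
  on <- t >= 30 & t <= 31
  pulse[on] <- 5 * 0.5 * (1 - cos(2 * pi * (t[on] - 30)))
  out <- compensate_movement(clean + pulse)
  keep <- !out$spike_mask
  # a residual constant offset past the event is out of every band of
  # interest; compare the waveform shape (first differences)
  rel <- sqrt(mean((diff(out$trace) - diff(clean))[keep[-1]]^2) /
                mean(diff(clean)[keep[-1]]^2))
  expect_lt(rel, 0.05)
})

test_that("movement corrupts the breathing estimate and compensation restores it", {
  # posture shifts (alternating DC steps) put strong low-frequency energy
  # into the breathing band; the spectral peak cannot be trusted until the
  # steps are removed in the time domain
  prf <- 20
  t <- (0:(120 * prf - 1)) / prf
  br_true <- 15
  clean <- sin(2 * pi * br_true / 60 * t)
  art <- numeric(length(t))
  s <- 1
  for (on in c(10, 25, 37, 55, 63, 81, 95, 110)) {
    art <- art + s * 8 * pmin(pmax((t - on) / 0.5, 0), 1)
    s <- -s
  }
  before <- estimate_br(clean + art, prf)
  after <- estimate_br(compensate_movement(clean + art)$trace, prf)
  expect_gt(abs(before$br - br_true), 2)
  expect_lt(abs(after$br - br_true), 1)
})

test_that("one-sigma rejection drops the discordant bin and keeps ties", {
  expect_equal(reject_outlier_bins(c(60, 61, 59, 120)), 1:3)
  expect_equal(reject_outlier_bins(rep(64, 5)), 1:5)
  # symmetric spread keeps a symmetric survivor set
  expect_equal(reject_outlier_bins(c(58, 60, 62, 64, 66)), 2:4)
  expect_warning(out <- reject_outlier_bins(c(60, 61)), "fewer than 3")
  expect_equal(out, 1:2)
})

test_that("threshold recalibration applies the empirical rule", {
  set.seed(13)
  traces <- replicate(5, cumsum(rnorm(200, 0, 0.05)), simplify = FALSE)
  th <- calibrate_threshold(traces)
  steps <- abs(unlist(lapply(traces, diff)))
  expect_equal(th, mean(steps) + 3 * sd(steps))
})
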
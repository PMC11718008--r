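test_that("valleys of a pure tone are its minima", {
  fs <- 20
  t <- (0:(10 * fs - 1)) / fs
  v <- detect_valleys(sin(2 * pi * 1 * t), fs = fs)
  expect_equal(length(v), 10)
  # minima of sin at 3/4 + k
  expect_equal(v, 0.75 + 0:9, tolerance = 0.02)
})

test_that("a clean cardiac train yields one valley per beat", {
  prof <- physio_profile(breathing_amplitude = 0, mean_ibi = 1.0, ibi_sd = 20,
                         seed = 31)
  gen <- generate_displacement(prof, duration = 60, prf = 20)
  v <- detect_valleys(gen$displacement$disp_mm, fs = 20)
  expect_gte(length(v), 59 - 1)
  expect_lte(length(v), 61)
})

test_that("shallow spurious dips are rejected by prominence", {
  fs <- 40
  t <- (0:(20 * fs - 1)) / fs
  x <- -cos(2 * pi * (t - 0.5))                   # valleys at k + 0.5 s
  x <- x + 0.05 * cos(2 * pi * 2 * (t - 0.5))     # 10%-deep dip mid-cycle
  v <- detect_valleys(x, fs = fs, upsample = 1)
  expect_equal(length(v), 20)
  expect_lt(max(abs(v - 0.5 - round(v - 0.5))), 0.05)
})

test_that("HRV metrics match their defining formulas", {
  h <- compute_hrv(cumsum(c(0, 0.800, 0.860, 0.865, 0.920)))
  expect_equal(h$ibi_series, c(800, 860, 865, 920))
  expect_equal(h$rmssd, sqrt(mean(c(60, 5, 55)^2)))
  expect_equal(h$rmssd, 47.0815, tolerance = 1e-4)
  expect_equal(h$pnn50, 200 / 3)
  expect_equal(h$sdrr, sqrt(mean((h$ibi_series - mean(h$ibi_series))^2)))
  expect_error(compute_hrv(c(0, 1, 2)), "at least 4")

  # zero variability
  h0 <- compute_hrv(seq(0, 5, by = 1))
  expect_equal(c(h0$rmssd, h0$sdrr, h0$pnn50), c(0, 0, 0))
})

test_that("HRV metrics scale and shift correctly", {
  set.seed(32)
  v <- cumsum(c(0, rnorm(40, 0.9, 0.05)))
  a <- compute_hrv(v)
  b <- compute_hrv(v + 17)            # shift invariance
  expect_equal(a$rmssd, b$rmssd)
  expect_equal(a$sdrr, b$sdrr)
  d <- compute_hrv(v * 2)             # scale equivariance of dispersion
  expect_equal(d$sdrr, 2 * a$sdrr)
  expect_equal(d$rmssd, 2 * a$rmssd)
  expect_true(a$pnn50 >= 0 && a$pnn50 <= 100)
})

test_that("interval artifact correction heals the canonical defects", {
  med <- 0.9
  v <- cumsum(c(0, rep(med, 10)))
  # spurious extra beat splits one interval
  v_sp <- sort(c(v, v[5] + 0.45))
  expect_equal(as.numeric(correct_ibi_artifacts(v_sp)), v, tolerance = 1e-9)
  # missed beat: interpolated back in (and flagged)
  v_miss <- v[-5]
  out <- correct_ibi_artifacts(v_miss)
  expect_equal(length(out), length(v))
  expect_equal(attr(out, "inserted"), v[5], tolerance = 1e-9)
  # duplicate detection 40 ms apart collapses to one beat
  v_dup <- sort(c(v, v[5] + 0.04))
  expect_equal(length(correct_ibi_artifacts(v_dup)), length(v))
  # clean series untouched
  expect_equal(as.numeric(correct_ibi_artifacts(v)), v)
})

test_that("morphology labels follow the template on clean waveforms", {
  for (kind in c("two_peak", "three_peak")) {
    prof <- physio_profile(breathing_amplitude = 0, mean_ibi = 0.9,
                           ibi_sd = 10, cardiac_template_kind = kind,
                           seed = 33)
    gen <- generate_displacement(prof, duration = 60, prf = 20)
    card <- bandpass_cardiac(gen$displacement$disp_mm, 20)
    lab <- classify_morphology(card, gen$truth$valley_times, fs = 20)
    expect_equal(lab,
                 if (kind == "two_peak") "typical_two_peak" else
                   "atypical_multi_peak")
  }
})

test_that("a mixed-shape recording is labelled indeterminate", {
  # half the cycles two-peak, half three-peak, joined end to end
  mk <- function(kind, seed) {
    prof <- physio_profile(breathing_amplitude = 0, mean_ibi = 0.9,
                           ibi_sd = 5, cardiac_template_kind = kind,
                           seed = seed)
    generate_displacement(prof, duration = 30, prf = 20)
  }
  a <- mk("two_peak", 34)
  b <- mk("three_peak", 34)
  x <- c(a$displacement$disp_mm, b$displacement$disp_mm)
  v <- c(a$truth$valley_times, 30 + b$truth$valley_times)
  lab <- classify_morphology(bandpass_cardiac(x, 20), v, fs = 20,
                             method = "per_cycle")
  expect_equal(lab, "indeterminate")
  expect_equal(classify_morphology(rep(0, 100), c(0, 1), fs = 20),
               "indeterminate")
})

test_that("bin fusion drops a corrupted bin and is identity on agreement", {
  set.seed(35)
  base <- cumsum(c(0.5, rep(0.9, 60)))
  bins <- lapply(1:5, function(i) base + rnorm(length(base), 0, 0.01))
  corrupted <- base[seq(1, length(base), by = 2)]    # half the beats
  all_b <- c(bins, list(corrupted))
  hr <- c(rep(66.7, 5), 33.3)
  fused <- fuse_bins(all_b, hr)
  expect_false(6 %in% fused$surviving_bins)
  expect_equal(length(fused$valley_times), length(base))
  expect_lt(max(abs(fused$valley_times - base)), 0.05)

  # identical bins: fusion is a no-op
  same <- fuse_bins(list(base, base, base), rep(66.7, 3))
  expect_equal(same$valley_times, base)
  # single usable bin passes through
  one <- fuse_bins(list(base, numeric()), c(66.7, NA))
  expect_equal(one$valley_times, base)
})

test_that("evaluation is exact on identity and shift fixtures", {
  set.seed(36)
  truth <- list(valley_times = cumsum(c(0.4, rnorm(50, 0.85, 0.03))),
                ibi_series = NULL, hr_true = NA)
  truth$ibi_series <- diff(truth$valley_times) * 1000
  truth$hr_true <- 60000 / mean(truth$ibi_series)

  ev <- evaluate_against_truth(truth$valley_times, truth)
  expect_equal(ev$summary$median_abs_ibi_error_ms, 0)
  expect_equal(ev$summary$n_missed, 0)
  expect_equal(ev$summary$hr_rel_error_pct, 0, tolerance = 1e-9)

  # constant shift: IBI errors stay zero, valley offsets show the shift
  ev2 <- evaluate_against_truth(truth$valley_times + 0.02, truth)
  expect_equal(ev2$summary$median_abs_ibi_error_ms, 0, tolerance = 1e-9)
  expect_equal(stats::median(ev2$valley_offsets), 20, tolerance = 1e-6)

  # one missing estimated beat: exactly one miss, the rest matched
  ev3 <- evaluate_against_truth(truth$valley_times[-10], truth)
  expect_equal(ev3$summary$n_missed, 1)
  expect_equal(ev3$summary$n_matched, length(truth$valley_times) - 1)
})
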
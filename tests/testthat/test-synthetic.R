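test_that("cardiac template meets its shape contract", {
  cases <- expand.grid(kind = c("two_peak", "three_peak"),
                       ratio = c(0.7, 1.0),
                       stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cases))) {
    tpl <- generate_cardiac_template(cases$kind[i], cases$ratio[i], 64L)
    n_max <- fmcwvitals:::count_cycle_peaks(as.numeric(tpl))
    expect_equal(n_max, if (cases$kind[i] == "two_peak") 2L else 3L,
                 info = paste(cases$kind[i], cases$ratio[i]))
    expect_equal(mean(tpl), 0, tolerance = 1e-12)
    expect_equal(max(abs(tpl)), 1)
    # the valley is the single global minimum
    expect_equal(sum(tpl == min(tpl)), 1L)
  }
  expect_error(generate_cardiac_template("four_peak"), "arg")
})

test_that("equal peak ratio gives equal peak heights", {
  tpl <- as.numeric(generate_cardiac_template("two_peak", 1.0, 256L))
  n <- length(tpl)
  left <- tpl[c(n, 1:(n - 1))]
  right <- tpl[c(2:n, 1)]
  peaks <- sort(tpl[tpl > left & tpl >= right], decreasing = TRUE)[1:2]
  expect_equal(peaks[1], peaks[2], tolerance = 1e-3)  # sampled-grid peaks
})

test_that("breathing-only displacement peaks at the breathing frequency", {
  prof <- physio_profile(breathing_rate = 15, cardiac_amplitude = 0,
                         breathing_harmonic_weights = c(0, 0, 0), seed = 4)
  gen <- generate_displacement(prof, duration = 120, prf = 20)
  psd <- fmcwvitals:::welch_psd(gen$displacement$disp_mm, 20)
  peak <- psd$freq_hz[which.max(psd$power)]
  expect_equal(peak, 0.25, tolerance = 0.02)
})

test_that("zero jitter yields a constant IBI sequence", {
  prof <- physio_profile(ibi_sd = 0, seed = 5)
  gen <- generate_displacement(prof, duration = 60, prf = 20)
  expect_lt(max(abs(gen$truth$ibi_series - prof$mean_ibi * 1000)), 1e-6)
})

test_that("ground truth is internally consistent and reproducible", {
  prof <- quiet_profile(seed = 6)
  g1 <- generate_displacement(prof, duration = 90, prf = 20)
  g2 <- generate_displacement(prof, duration = 90, prf = 20)
  expect_identical(g1$displacement$disp_mm, g2$displacement$disp_mm)
  expect_equal(g1$truth$ibi_series, diff(g1$truth$valley_times) * 1000)
  expect_equal(g1$truth$hr_true, 60000 / mean(g1$truth$ibi_series))
})

test_that("a strong breathing second harmonic can dominate the cardiac band", {
  # deep-breathing regime: the band-limited power of the 2x-breathing line
  # exceeds the whole cardiac contribution
  prof <- physio_profile(breathing_rate = 17, breathing_amplitude = 2,
                         breathing_harmonic_weights = c(0.25, 0.02, 0.01),
                         mean_ibi = 60 / 57, seed = 7)
  gen <- generate_displacement(prof, duration = 120, prf = 20)
  card_band <- bandpass_cardiac(gen$displacement$disp_mm, 20)
  psd <- fmcwvitals:::welch_psd(card_band, 20)
  f2 <- 2 * 17 / 60
  near_h2 <- abs(psd$freq_hz - f2) < 0.05
  cardiac <- psd$freq_hz > 0.8 & psd$freq_hz < 6
  expect_gt(max(psd$power[near_h2]), max(psd$power[cardiac]))
})

test_that("out-of-band physiology is rejected", {
  expect_error(physio_profile(mean_ibi = 2), "cardiac fundamental")
  expect_error(physio_profile(breathing_rate = 3), "breathing fundamental")
})
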
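# helper: run a displacement trace through respiration + decomposition
chain_to_plan <- function(trace, prf = 20) {
  resp <- estimate_br(trace, prf)
  card <- bandpass_cardiac(trace, prf)
  imfs <- vmd_decompose(card, prf, alpha = 40000)
  list(resp = resp, imfs = imfs, plan = select_harmonics(imfs, resp))
}

test_that("shallow breathing: the strongest in-band mode is the cardiac fundamental", {
  prof <- physio_profile(breathing_rate = 17, breathing_amplitude = 0.4,
                         breathing_harmonic_weights = c(0.03, 0.01, 0.005),
                         mean_ibi = 1.0, seed = 21)
  gen <- generate_displacement(prof, duration = 120, prf = 20)
  out <- chain_to_plan(compensate_movement(gen$displacement$disp_mm)$trace)
  expect_false(out$plan$refused)
  expect_equal(out$plan$fundamental_hz, 1.0, tolerance = 0.07)
  expect_equal(out$plan$mode_indices[1], which.max(out$imfs$powers))
  expect_gte(length(out$plan$mode_indices), 2)
})

test_that("deep breathing: the strongest mode (2x breathing) is rejected", {
  prof <- physio_profile(breathing_rate = 17, breathing_amplitude = 2,
                         breathing_harmonic_weights = c(0.25, 0.06, 0.02),
                         mean_ibi = 60 / 57, seed = 22)
  gen <- generate_displacement(prof, duration = 120, prf = 20)
  out <- chain_to_plan(compensate_movement(gen$displacement$disp_mm)$trace)
  strongest <- which.max(out$imfs$powers)
  # the strongest mode sits on twice the breathing rate...
  expect_equal(out$imfs$center_frequencies[strongest],
               2 * out$resp$peak_frequency, tolerance = 0.05)
  # ...and is not selected; the true fundamental (57 beats/min) is
  expect_false(out$plan$refused)
  expect_false(strongest %in% out$plan$mode_indices)
  expect_equal(out$plan$fundamental_hz, 57 / 60, tolerance = 0.07)
})

test_that("a fundamental sitting on a breathing multiple triggers refusal", {
  prof <- physio_profile(breathing_rate = 30, mean_ibi = 1.0, seed = 23)
  gen <- generate_displacement(prof, duration = 120, prf = 20)
  out <- chain_to_plan(compensate_movement(gen$displacement$disp_mm)$trace)
  expect_true(out$plan$refused)
  expect_match(out$plan$reason, "breathing multiple")
  expect_error(reconstruct(out$plan, out$imfs), "cannot be reconstructed")
})

test_that("no selected component sits on a breathing multiple", {
  for (seed in c(31, 32, 33)) {
    prof <- physio_profile(breathing_rate = 10 + 2 * (seed - 30),
                           mean_ibi = 0.75 + 0.05 * (seed - 30), seed = seed)
    gen <- generate_displacement(prof, duration = 120, prf = 20)
    out <- chain_to_plan(compensate_movement(gen$displacement$disp_mm)$trace)
    if (out$plan$refused) next
    cf <- out$imfs$center_frequencies[out$plan$mode_indices]
    for (k in 1:4) {
      excl <- k * out$resp$peak_frequency
      expect_true(all(abs(cf - excl) > harmonic_tolerance(excl)),
                  info = paste("seed", seed, "order", k))
    }
  }
})

test_that("reconstruction is the exact sum of the planned modes", {
  prof <- quiet_profile(seed = 24)
  gen <- generate_displacement(prof, duration = 90, prf = 20)
  out <- chain_to_plan(gen$displacement$disp_mm)
  w <- reconstruct(out$plan, out$imfs)
  expect_equal(w$trace,
               rowSums(out$imfs$modes[, out$plan$mode_indices, drop = FALSE]))
  expect_equal(w$hr_spectral, 60 * w$fundamental)
  expect_gte(length(w$harmonic_orders_used), 2)
})

test_that("reconstruction valleys match ground truth closely on clean input", {
  prof <- quiet_profile(seed = 25)
  gen <- generate_displacement(prof, duration = 120, prf = 20)
  out <- chain_to_plan(gen$displacement$disp_mm)
  w <- reconstruct(out$plan, out$imfs)
  v <- detect_valleys(w)
  ev <- evaluate_against_truth(v, gen$truth)
  expect_lt(abs(stats::median(ev$valley_offsets)), 40)
})

test_that("the IBI series is stable when the highest harmonic is dropped", {
  # dropping the 4th harmonic shifts every valley by the same shape offset
  # (~2% of the cycle, intrinsic to any sharp-valleyed template); what must
  # be stable for HRV is the interval series, which is shift-invariant
  prof <- physio_profile(breathing_rate = 12, mean_ibi = 0.8, ibi_sd = 5,
                         breathing_amplitude = 0.1, seed = 26)
  gen <- generate_displacement(prof, duration = 120, prf = 20)
  out <- chain_to_plan(compensate_movement(gen$displacement$disp_mm)$trace)
  plan <- out$plan
  expect_false(plan$refused)
  expect_equal(max(plan$harmonic_orders), 4L)
  v_full <- detect_valleys(reconstruct(plan, out$imfs))
  plan2 <- plan
  keep <- plan$harmonic_orders < 4
  plan2$mode_indices <- plan$mode_indices[keep]
  plan2$harmonic_orders <- plan$harmonic_orders[keep]
  v_red <- detect_valleys(reconstruct(plan2, out$imfs))
  matched <- fmcwvitals:::match_valleys(v_full, v_red, 0.25)
  ok <- !is.na(matched)
  d_ibi <- diff(v_red[matched[ok]]) - diff(v_full[ok])
  expect_lt(stats::median(abs(d_ibi)) * 1000, 10)
})
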
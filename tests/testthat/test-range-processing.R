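test_that("static scatterer lands in the closed-form range bin", {
  cfg <- radar_config()
  for (r in c(0.12, 0.27)) {
    cube <- synthesize_cube(rep(0, 10), r, cfg)
    rp <- cube |> remove_dc() |> average_chirps() |> range_fft()
    expect_equal(which.max(Mod(rp$values[1, ])) - 1L, range_to_bin(r, cfg),
                 info = paste("range", r))
  }
  # beyond max range is rejected (aliased beat frequency)
  expect_error(synthesize_cube(rep(0, 4), 1.0, cfg), "max_range")
})

test_that("all chirps of a frame are identical without slow-time modulation", {
  cube <- synthesize_cube(rep(0, 5), 0.15, radar_config())
  expect_equal(cube$samples[1, 1, ], cube$samples[1, 32, ])
  expect_equal(cube$samples[3, 5, ], cube$samples[3, 20, ])
})

test_that("cube synthesis is bit-identical under a fixed seed", {
  d <- sin(2 * pi * 0.25 * (0:99) / 20)
  c1 <- synthesize_cube(d, 0.12, phase_noise_sd = 0.05,
                        amplitude_noise_sd = 0.5, seed = 3)
  c2 <- synthesize_cube(d, 0.12, phase_noise_sd = 0.05,
                        amplitude_noise_sd = 0.5, seed = 3)
  expect_identical(c1$samples, c2$samples)
})

test_that("DC removal zeroes the fast-time mean and preserves AC content", {
  cfg <- radar_config()
  cube <- synthesize_cube(rep(0, 4), 0.2, cfg)
  cube$samples <- cube$samples + 3           # inject a DC offset
  out <- remove_dc(cube)
  mu <- apply(out$samples, c(1, 2), mean)
  expect_lt(max(abs(mu)), 1e-12)
  # x = 3 + cos(2 pi f t): subtraction recovers the cosine
  t <- (0:63) / 1e6
  x <- 3 + cos(2 * pi * 62500 * t)
  cube2 <- structure(list(samples = array(x, c(1, 1, 64)), config = cfg,
                          timestamps = 0), class = "radar_cube")
  rec <- remove_dc(cube2)$samples[1, 1, ]
  expect_equal(rec, cos(2 * pi * 62500 * t) - mean(cos(2 * pi * 62500 * t)),
               tolerance = 1e-9)
})

test_that("chirp averaging suppresses white phase noise like 1/sqrt(n)", {
  # variance-of-mean oracle: averaging 32 iid phase perturbations improves
  # phase variance by 10 log10(32) ~ 15 dB
  cfg <- radar_config()
  n_frames <- 400
  cube <- synthesize_cube(rep(0, n_frames), 0.12, cfg, phase_noise_sd = 0.05,
                          seed = 9)
  avg <- average_chirps(cube)
  rp <- range_fft(avg)
  ph_avg <- Arg(rp$values[, 5])
  one <- structure(list(samples = cube$samples[, 1, , drop = FALSE],
                        config = cfg, timestamps = cube$timestamps),
                   class = "radar_cube")
  one$samples <- array(one$samples, c(n_frames, 1, 64))
  ph_one <- Arg(range_fft(average_chirps(one))$values[, 5])
  gain_db <- 10 * log10(stats::var(ph_one) / stats::var(ph_avg))
  expect_equal(gain_db, 10 * log10(32), tolerance = 1)
})

test_that("range FFT matches a brute-force DFT", {
  cfg <- radar_config()
  cube <- synthesize_cube(sin(2 * pi * 0.3 * (0:19) / 20), c(0.12, 0.24),
                          cfg, seed = 2)
  avg <- average_chirps(remove_dc(cube))
  rp <- range_fft(avg)
  for (fr in c(1, 10)) {
    x <- avg[fr, ]
    dft <- vapply(0:31, function(k) {
      sum(x * exp(-2i * pi * k * (0:63) / 64))
    }, complex(1))
    expect_equal(rp$values[fr, ], dft, tolerance = 1e-9)
  }
  # two scatterers 12 cm apart resolve into two separated peaks
  mag <- Mod(rp$values[1, ])
  pk <- order(mag, decreasing = TRUE)[1:2]
  expect_setequal(sort(pk) - 1L, c(4L, 8L))
})

test_that("displacement round-trips through the full forward model", {
  cfg <- radar_config()
  t <- (0:(60 * 20 - 1)) / 20
  d <- 1 * sin(2 * pi * 0.25 * t)
  cube <- synthesize_cube(d, 0.12, cfg)
  disp <- cube |> remove_dc() |> average_chirps() |> range_fft() |>
    extract_displacement(bin_ids = 4)
  rel_rms <- sqrt(mean((disp$bin4_mm - d)^2) / mean(d^2))
  expect_lt(rel_rms, 0.01)

  # doubling the displacement doubles the recovery (linearity within 2%)
  cube2 <- synthesize_cube(2 * d, 0.12, cfg)
  disp2 <- cube2 |> remove_dc() |> average_chirps() |> range_fft() |>
    extract_displacement(bin_ids = 4)
  expect_equal(disp2$bin4_mm, 2 * disp$bin4_mm, tolerance = 0.02)
})

test_that("phase unwrapping tracks multi-wavelength ramps", {
  cfg <- radar_config()
  n <- 400
  d <- seq(0, 4, length.out = n)           # ~1.6 wavelengths of motion
  cube <- synthesize_cube(d, 0.12, cfg)
  disp <- cube |> remove_dc() |> average_chirps() |> range_fft() |>
    extract_displacement(bin_ids = 4)
  expect_lt(max(abs(disp$bin4_mm - d)), 0.05)
  expect_lt(max(abs(diff(disp$bin4_mm) - diff(d))), 0.01)  # no 2 pi jumps
})

test_that("a static scene extracts to identically zero displacement", {
  cube <- synthesize_cube(rep(0, 50), c(0.12, 0.18), radar_config())
  disp <- cube |> remove_dc() |> average_chirps() |> range_fft() |>
    extract_displacement(bin_ids = c(4, 6))
  expect_lt(max(abs(fmcwvitals:::bin_matrix(disp))), 1e-9)
  expect_error(extract_displacement(
    cube |> remove_dc() |> average_chirps() |> range_fft(), bin_ids = 40),
    "out of bounds")
})
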
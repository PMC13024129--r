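test_that("clutter suppression zeroes the slow-time mean and is idempotent", {
  cfg <- radar_config(n_chirps = 64L)
  mot <- chest_motion(R0 = 0.5, n_samples = 64L)
  cube <- simulate_radar_cube(mot, cfg, clutter_amp = 2,
                              dc_offset = complex(real = 1, imaginary = -2))
  cs <- suppress_clutter(cube)
  expect_lt(max(Mod(colMeans(cs))), 1e-9 * max(Mod(cube)))
  expect_equal(unclass(suppress_clutter(cs)), unclass(cs), ignore_attr = TRUE)
  # chirp-invariant offsets leave the output unchanged (exact)
  shifted <- cube + complex(real = 0.7, imaginary = 0.3)
  attributes(shifted) <- attributes(cube)
  expect_equal(unclass(suppress_clutter(shifted)), unclass(cs), ignore_attr = TRUE)
  one <- cube[1, , , drop = FALSE]
  expect_error(suppress_clutter(one), "at least 2 chirps")
})

test_that("DC removal subtracts a sliding mean with exact edge behaviour", {
  x <- rep(complex(real = 2, imaginary = -1), 50)
  expect_true(all(Mod(remove_dc_offset(x, 11)) < 1e-12))
  y <- complex(real = rnorm(40), imaginary = rnorm(40))
  expect_equal(remove_dc_offset(y, 40), y - mean(y))
  # short-period oscillation passes nearly unattenuated through a long window
  t <- 1:400
  tone <- exp(2i * pi * t / 8)
  out <- remove_dc_offset(tone, 201)
  expect_lt(max(Mod(out - tone)) / max(Mod(tone)), 0.05)
  expect_error(remove_dc_offset(y, 0), "window_len")
})

test_that("beamforming weights and coherent gain follow the array factor", {
  lam <- 0.0039
  geom <- array_geometry(4L, wavelength = lam)
  expect_true(all(abs(Mod(steering_weights(geom, 0.7)) - 1) < 1e-12))
  expect_true(all(steering_weights(geom, 0) == 1))
  # unit source at theta0, steered to theta0 -> gain 4
  theta0 <- 10 * pi / 180
  src <- exp(-1i * 2 * pi * (geom$spacing / lam) * (0:3) * sin(theta0))
  cube <- array(0i, c(5, 1, 4))
  for (ch in 1:4) cube[, 1, ch] <- src[ch]
  bf <- beamform(cube, geom, theta0)
  expect_lt(abs(Mod(bf[1, 1]) - 4), 1e-9)
  # theta = 0 steering reduces to the plain channel sum
  expect_equal(beamform(cube, geom, 0)[1, 1], sum(src))
  # half-wavelength 4-element array has a null 30 degrees off a broadside source
  cube0 <- array(1 + 0i, c(3, 1, 4))
  expect_lt(Mod(beamform(cube0, geom, asin(0.5))[1, 1]), 0.05)
  expect_error(beamform(cube0[, , 1:3, drop = FALSE], geom, 0), "channel count")
})

test_that("range-angle selection recovers a clean target and breaks ties low", {
  cfg <- radar_config(n_chirps = 1024L)
  mot <- chest_motion(R0 = 0.5625, n_samples = 1024L, heart_rate = 1.2,
                      cardiac_amp = 2e-4, resp_amp = 8e-4)
  theta0 <- 10 * pi / 180
  cube <- simulate_radar_cube(mot, cfg, clutter_amp = 1, target_angle = theta0)
  geom <- array_geometry(4L, wavelength = cfg$wavelength)
  sel <- select_range_angle(suppress_clutter(cube), geom)
  bin <- as.integer(round(2 * cfg$frequency_slope * 0.5625 / 299792458 /
                            (cfg$fast_rate / cfg$n_fast))) + 1L
  expect_identical(sel$range_bin, bin)
  expect_equal(sel$theta, theta0)
  zero <- cube
  zero[] <- 0i
  attributes(zero) <- attributes(cube)
  expect_error(select_range_angle(zero, geom), "no target found")
})

test_that("DACM accumulates the printed cross-multiplied increments", {
  expect_error(dacm_demodulate(1:5, 1:4), "equal length")
  expect_error(dacm_demodulate(c(1, 0), c(0, 0)), "invalid I/Q")
  # constant I/Q -> zero phase
  expect_equal(dacm_demodulate(rep(2, 10), rep(1, 10))$phi, rep(0, 10))
  # constant-step unit circle: Phi[n] = (n - 1) sin(step)
  k <- 1:200
  ph <- dacm_demodulate(cos(0.1 * k), sin(0.1 * k))$phi
  expect_lt(max(abs(ph - (k - 1) * sin(0.1))), 1e-10)
  # slow ramp repeatedly crossing +/- pi stays continuous and tracks the
  # cumulative true phase
  tru <- seq(0, by = 0.02, length.out = 600) - pi / 2
  ph2 <- dacm_demodulate(cos(tru), sin(tru))$phi
  expect_lt(max(abs(ph2 - (tru - tru[1]))), 1e-3)
  expect_lt(max(abs(diff(ph2))), 0.05)                     # no wrap jumps
})

test_that("pulse-wave extraction keeps the heart band and rejects respiration", {
  fs <- 200
  t <- (0:3999) / fs
  y <- extract_rpw(sin(2 * pi * 1.2 * t), band = c(0.8, 10), fs = fs, fs_out = fs)
  expect_lt(abs(max(abs(y[500:3500])) - 1), 0.02)
  resp <- extract_rpw(sin(2 * pi * 0.25 * t), band = c(0.8, 10), fs = fs, fs_out = fs)
  expect_lt(20 * log10(max(abs(resp[500:3500]))), -20)
  expect_true(all(extract_rpw(numeric(100), fs = fs) == 0))
  expect_error(extract_rpw(y, band = c(0.8, 150), fs = fs), "Nyquist")
})

test_that("windowing tiles series with the contracted hop", {
  w <- segment_windows(seq_len(3000), 1000L, overlap = 0.5)
  expect_length(w, 5)
  expect_true(all(lengths(w) == 1000))
  w0 <- segment_windows(seq_len(3000), 1000L, overlap = 0)
  expect_length(w0, 3)
  expect_identical(w0[[2]][1], 1001L)
  expect_identical(segment_windows(seq_len(10), 100L), list())
})

test_that("standardization gives zero mean, unit sd and affine invariance", {
  x <- rnorm(500)
  z <- standardize_window(x)
  expect_lt(abs(mean(z)), 1e-6)
  expect_lt(abs(sd(z) - 1), 1e-3)
  expect_true(all(standardize_window(rep(3.3, 100)) == 0))
  expect_equal(standardize_window(2.5 * x + 7), z, tolerance = 1e-6)
})

test_that("full radar chain recovers the cardiac waveform", {
  cfg <- radar_config(n_chirps = 4096L)
  mot <- chest_motion(R0 = 0.5625, n_samples = 4096L, heart_rate = 1.2,
                      cardiac_amp = 2e-4, resp_amp = 8e-4)
  cube <- simulate_radar_cube(mot, cfg, clutter_amp = 2,
                              dc_offset = complex(real = 0.5, imaginary = -0.3),
                              target_angle = 10 * pi / 180)
  out <- preprocess_cube(cube)
  ref <- extract_rpw(mot$cardiac - mean(mot$cardiac), band = c(0.8, 10),
                     fs = mot$fs, fs_out = 100)
  n <- min(length(out$rpw), length(ref))
  expect_gte(cor(out$rpw[1:n], ref[1:n]), 0.99)
})
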
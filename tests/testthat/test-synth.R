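test_that("arterial waveform anchors per-cycle extrema at SBP/DBP", {
  p <- hemo_params(sbp = 120, dbp = 80, heart_rate = 1.2)
  a <- generate_abp_waveform(p, 1000L, 100, rng_seed = 1)
  # full cycles only (cycle length = fs / hr samples)
  cyc <- floor((seq_along(a) - 1) * 1.2 / 100)
  full <- table(cyc)
  full <- names(full)[full >= floor(100 / 1.2)]
  for (k in full) {
    seg <- a[cyc == as.integer(k)]
    expect_lt(abs(max(seg) - 120), 1)
    expect_lt(abs(min(seg) - 80), 1)
  }
  expect_true(any(diff(a[1:40]) > 0))  # systolic upstroke exists
})

test_that("non-physiological parameters are rejected", {
  expect_error(hemo_params(sbp = 100, dbp = 100), "sbp > dbp")
  expect_error(hemo_params(sbp = 120, dbp = 80, heart_rate = 0.2), "heart_rate")
  p <- hemo_params()
  expect_error(generate_abp_waveform(p, 10L, 100), "full cardiac cycle")
})

test_that("generators are deterministic given a seed", {
  p <- hemo_params(noise_sd = 1)
  expect_identical(generate_abp_waveform(p, 500L, 100, rng_seed = 9),
                   generate_abp_waveform(p, 500L, 100, rng_seed = 9))
  ds1 <- make_dataset(3, 4, corrupt_fraction = 0.25, rng_seed = 5, L = 300)
  ds2 <- make_dataset(3, 4, corrupt_fraction = 0.25, rng_seed = 5, L = 300)
  expect_identical(ds1, ds2)
  # generators restore the caller's RNG state
  set.seed(123); r1 <- runif(1)
  set.seed(123); invisible(make_dataset(3, 2, rng_seed = 7, L = 300)); r2 <- runif(1)
  expect_identical(r1, r2)
})

test_that("radar pulse wave preserves arterial morphology", {
  p <- hemo_params(sbp = 120, dbp = 80, heart_rate = 1.0)
  a <- generate_abp_waveform(p, 600L, 100, rng_seed = 2)
  r0 <- derive_rpw_from_abp(a, p, smooth_k = 1L)           # identity smoothing
  expect_equal(which.max(a[1:100]), which.max(r0[1:100]))
  p2 <- hemo_params(sbp = 120, dbp = 80, heart_rate = 1.0, noise_sd = 0.05)
  rn <- derive_rpw_from_abp(a, p2, rng_seed = 3)
  rc <- derive_rpw_from_abp(a, hemo_params(120, 80, 1.0))
  expect_gte(cor(rn, rc), 0.95)
  const <- derive_rpw_from_abp(rep(5, 100), hemo_params())
  expect_true(all(const == const[1]))                       # degenerate pass-through
})

test_that("simulated radar cube follows the displacement-to-phase model", {
  cfg <- radar_config(n_chirps = 256L)
  still <- chest_motion(R0 = 0.5, n_samples = 256L, cardiac_amp = 0, resp_amp = 0)
  cube <- simulate_radar_cube(still, cfg)
  for (m in 2:5) expect_equal(cube[m, , ], cube[1, , ])     # static target

  mot <- chest_motion(R0 = 0.5625, n_samples = 256L, heart_rate = 1.3,
                      cardiac_amp = 3e-4, resp_amp = 0)
  cube <- simulate_radar_cube(mot, cfg)
  # ideal reference demodulation at the target bin recovers 4 pi x / lambda
  rc <- radarbp::range_compress(cube)
  bin <- round(2 * cfg$frequency_slope * 0.5625 / 299792458 /
                 (cfg$fast_rate / cfg$n_fast)) + 1L
  s <- rc[, bin, 1]
  phi <- Arg(s * Conj(s[1]))
  pred <- 4 * pi * (mot$displacement - mot$displacement[1]) / cfg$wavelength
  expect_lt(max(abs(phi - pred)), 1e-3 + 0.02 * max(abs(pred)))

  cube2 <- simulate_radar_cube(still, cfg, clutter_amp = 1.5)
  mu <- colMeans(cube2)
  one <- simulate_radar_cube(still, cfg, clutter_amp = 1.5)[1, , ]
  clutter_only <- one - simulate_radar_cube(still, cfg, clutter_amp = 0)[1, , ]
  expect_lt(max(Mod(mu - simulate_radar_cube(still, cfg, clutter_amp = 0)[1, , ] -
                      clutter_only)), 1e-9)
  expect_error(simulate_radar_cube(chest_motion(n_samples = 8L), cfg), "n_chirps")
})

test_that("corruption operators implement their named distortions", {
  x <- pulse_train(1.2, 600L)
  expect_identical(inject_corruption(x, corruption_spec("spike", 0), 1),
                   list(x = x, label = "clean"))
  sp <- inject_corruption(x, corruption_spec("spike", 1), 2)
  expect_identical(sp$label, "corrupted")
  expect_gte(max(abs(sp$x - x)), 5 * sd(x))
  dr <- inject_corruption(x, corruption_spec("dropout", 1), 3)$x
  z <- rle(dr == 0)
  expect_gte(max(z$lengths[z$values]), 5)
  expect_error(corruption_spec("bogus"), "unknown corruption kind")
})

test_that("dataset assembly counts windows and corruption labels exactly", {
  ds <- make_dataset(5, 8, corrupt_fraction = 0.2, rng_seed = 3, L = 300)
  expect_equal(dataset_size(ds), 40)
  expect_equal(sum(ds$corrupt), round(0.2 * 40))
  clean <- make_dataset(3, 3, corrupt_fraction = 0, rng_seed = 3, L = 300)
  expect_false(any(clean$corrupt))
  expect_error(make_dataset(2, 5), "at least 3")
  tmp <- tempfile(fileext = ".rds")
  write_dataset(ds, tmp)
  expect_identical(read_dataset(tmp), ds)
  unlink(tmp)
})

test_that("pre-screening separates clean from corrupted windows", {
  ds <- make_dataset(6, 20, corrupt_fraction = 0.4, rng_seed = 8, L = 500)
  s <- apply(ds$rpw, 1, function(w) prescreen_score(w, ds$fs)$s_p)
  expect_gte(sum(!ds$corrupt) + sum(ds$corrupt), 100)
  expect_gt(mean(s[!ds$corrupt]), mean(s[ds$corrupt]) + 0.05)
})
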
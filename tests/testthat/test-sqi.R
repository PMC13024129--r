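test_that("pre-screening indicators behave on canonical signals", {
  fs <- 100
  t <- (0:999) / fs
  clean <- standardize_window(sin(2 * pi * 1.2 * t) + 0.3 * sin(2 * pi * 2.4 * t))
  ps <- prescreen_score(clean, fs)
  expect_gte(ps$hr_band_ratio, 0.9)
  expect_gte(ps$interval_regularity, 0.9)
  expect_true(all(unlist(ps) >= 0 & unlist(ps) <= 1))
  # white noise: weak periodicity (seeded Monte-Carlo average)
  set.seed(77)
  per <- replicate(50, prescreen_score(rnorm(1000), fs)$periodicity_strength)
  expect_lte(mean(per), 0.2)
  # degenerate constant window
  expect_identical(prescreen_score(rep(1, 1000), fs)$s_p, 0)
})

test_that("VAE objective matches its closed forms", {
  x <- matrix(rnorm(2 * 100), 2)
  l0 <- vae_loss(x, x, matrix(0, 2, 64), matrix(0, 2, 64), beta = 1)
  expect_equal(l0$total, 0)
  # mu = 1 on all 64 dims, logvar = 0, perfect reconstruction -> KL = 32
  l1 <- vae_loss(x, x, matrix(1, 2, 64), matrix(0, 2, 64), beta = 1)
  expect_equal(l1$kl, 32)
  expect_equal(l1$total, 32)
  # beta = 0 ignores latent statistics
  l2 <- vae_loss(x, x + 0.1, matrix(5, 2, 64), matrix(2, 2, 64), beta = 0)
  expect_equal(l2$total, l2$rec)
  expect_equal(l2$rec, mean(0.1^2))
  expect_error(vae_loss(x, x * NA, matrix(0, 2, 4), matrix(0, 2, 4)), "non-finite")
})

test_that("KL warm-up is linear from 0.01 to 0.5 over 30 epochs", {
  expect_equal(beta_schedule(1), 0.01)
  expect_equal(beta_schedule(30), 0.5)
  expect_equal(beta_schedule(45), 0.5)
  mid <- beta_schedule(15)
  expect_equal(mid, 0.01 + (14 / 29) * 0.49)
})

test_that("stage-1 selection takes the top 35% by pre-screening score", {
  s <- runif(200)
  idx <- prescreen_select(s, 0.35)
  expect_length(idx, 70)
  expect_equal(sort(s[idx], decreasing = TRUE), sort(s, decreasing = TRUE)[1:70])
})

test_that("two-stage VAE training reduces the loss and freezes calibration", {
  fx <- tiny_vae_fixture()
  h <- fx$vae$history
  expect_equal(h$beta[1], 0.01)
  expect_lt(h$rec[nrow(h)], h$rec[1])
  expect_setequal(unique(h$stage), c(1, 2))
  cal <- fx$vae$calibration
  expect_length(cal$hq_center, fx$vae$cfg$latent)
  expect_gt(cal$median_e, 0)
  expect_error(fit_vae(matrix(numeric(0), 0, 400)), "empty input|at least one")
})

test_that("component scores follow their normalizations and monotonicity", {
  fx <- tiny_vae_fixture()
  comp <- component_scores(fx$Z, fx$vae, fs = fx$ds$fs)
  cal <- fx$vae$calibration
  expect_equal(unname(comp$components[, "S_R"]),
               pmin(1, exp(-comp$err / cal$median_e)), tolerance = 1e-12)
  expect_equal(unname(comp$components[, "S_L"]),
               pmin(1, exp(-comp$dist / cal$median_d)), tolerance = 1e-12)
  # zero-error / zero-distance anchors of the exponential map
  expect_equal(exp(-0 / cal$median_e), 1)
  # monotonicity on grids
  eg <- seq(0, 5 * cal$median_e, length.out = 30)
  expect_true(all(diff(exp(-eg / cal$median_e)) <= 0))
  expect_true(all(comp$components >= 0 & comp$components <= 1))
  # reconstruction consistency separates corruption classes
  expect_gt(mean(comp$components[!fx$ds$corrupt, "S_R"]),
            mean(comp$components[fx$ds$corrupt, "S_R"]))
  bad <- build_vae(vae_config("tiny", input_len = 400), 1)
  expect_error(component_scores(fx$Z, bad), "uncalibrated")
})

test_that("quality fusion is the exact weighted sum", {
  w <- sqi_weights()
  expect_equal(unname(w), c(0.35, 0.15, 0.30, 0.20))
  expect_equal(fuse_sqi(c(1, 1, 1, 1)), 1.0)
  expect_equal(fuse_sqi(c(1, 0, 0, 0)), 0.35)
  expect_equal(fuse_sqi(c(0, 1, 0, 0)), 0.15)
  expect_equal(fuse_sqi(c(0, 0, 1, 0)), 0.30)
  expect_equal(fuse_sqi(c(0, 0, 0, 1)), 0.20)
  m <- matrix(runif(40), 10, 4)
  expect_equal(fuse_sqi(m), as.numeric(m %*% w))
})

test_that("adaptive threshold retains the top fraction up to ties", {
  s <- 1:100
  tau <- adaptive_threshold(s, 0.8)
  expect_equal(sum(s >= tau), 80)
  expect_equal(adaptive_threshold(rep(0.5, 20), 0.8), 0.5)
  expect_true(all(rep(0.5, 20) >= adaptive_threshold(rep(0.5, 20), 0.8)))
  expect_equal(adaptive_threshold(s, 1.0), 1)
})

test_that("dataset screening applies a frozen scorer with a leakage guard", {
  fx <- tiny_vae_fixture()
  splits <- split_by_subject(fx$ds, rng_seed = 1)
  vae_ok <- fx$vae
  vae_ok$trained_on <- unique(splits$train$subject)
  scr <- screen_dataset(splits, vae_ok, retain_fraction = 0.8)
  n_tr <- dataset_size(splits$train)
  expect_gte(dataset_size(scr$train), ceiling(0.8 * n_tr))
  expect_lt(abs(mean(scr$train$weight) - 1), 1e-6)
  vae_leak <- fx$vae
  vae_leak$trained_on <- unique(fx$ds$subject)      # includes val/test subjects
  expect_error(screen_dataset(splits, vae_leak), "leakage guard")
})

test_that("discrimination metrics match closed-form cases", {
  sep <- c(rnorm(50, 5), rnorm(50, -5))
  lab <- rep(c(TRUE, FALSE), each = 50)
  ev <- evaluate_sqi(sep, lab)
  expect_equal(ev$roc_auc, 1.0)
  expect_equal(ev$f1, 1.0)
  set.seed(11)
  s <- rnorm(1000)
  l <- sample(c(TRUE, FALSE), 1000, replace = TRUE)
  expect_lt(abs(evaluate_sqi(s, l)$roc_auc - 0.5), 0.05)
  a1 <- evaluate_sqi(s, l)$roc_auc
  expect_equal(evaluate_sqi(-s, l)$roc_auc, 1 - a1, tolerance = 1e-12)
  expect_error(evaluate_sqi(s, rep(TRUE, 1000)), "both classes")
})
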
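test_that("Huber loss matches its closed form and is continuous at the knot", {
  expect_equal(huber(0.5, 0, delta = 1), 0.125)
  expect_equal(huber(2, 0, delta = 1), 1.5)
  expect_equal(huber(1, 0, delta = 1), 0.5)
  expect_equal(huber(-2, 0, delta = 1), 1.5)                  # symmetry
  # quadratic branch == 0.5 MSE on a grid inside |e| <= delta
  e <- seq(-1, 1, by = 0.05)
  expect_equal(vapply(e, function(x) huber(x, 0, 1), numeric(1)), 0.5 * e^2)
  # gradient continuity at |e| = delta (central finite differences)
  fd <- function(x, h = 1e-6) (huber(x + h, 0, 1) - huber(x - h, 0, 1)) / (2 * h)
  expect_lt(abs(fd(1) - 1), 1e-4)
  expect_lt(abs(fd(1 - 1e-4) - fd(1 + 1e-4)), 1e-3)
})

test_that("BP loss combines weighted Huber terms with sample weights", {
  pred <- list(sbp = 2, dbp = 0.5)
  targ <- list(sbp = 0, dbp = 0)
  expect_equal(bp_loss(pred, targ, loss_config()), 2 * 1.5 + 0.125)
  expect_equal(bp_loss(list(sbp = c(1, 1), dbp = c(2, 2)),
                       list(sbp = c(1, 1), dbp = c(2, 2)), loss_config()), 0)
  w <- c(0.5, 2)
  p2 <- list(sbp = c(2, 3), dbp = c(1, 0))
  t2 <- list(sbp = c(0, 1), dbp = c(0, 0))
  expect_equal(bp_loss(p2, t2, loss_config(), 2 * w),
               2 * bp_loss(p2, t2, loss_config(), w))       # linearity in weights
})

test_that("waveform loss is affine-invariant after instance normalization", {
  set.seed(1)
  p <- matrix(rnorm(3 * 100), 3)
  expect_lt(abs(abp_recon_loss(p, 2.5 * p + 7)), 1e-6)
  expect_gt(abp_recon_loss(p, -p), 0)
  # closed-form Smooth-L1 on a fixed small normalized difference
  a <- instance_normalize(matrix(c(0, 0.5, 1, -0.5, 0.25, -1), 1))
  b <- a * 0
  d <- a - b
  expect_equal(abp_recon_loss(a, matrix(rep(0, 6), 1)),
               mean(ifelse(abs(d) <= 1, 0.5 * d^2, abs(d) - 0.5)),
               tolerance = 1e-5)
})

test_that("total loss composes exactly", {
  pred <- list(sbp = 2, dbp = 0.5, abp = matrix(1:10, 1))
  targ <- list(sbp = 0, dbp = 0, abp = matrix(rep(1, 10), 1))
  cfg0 <- loss_config(lambda_abp = 0)
  l0 <- total_loss(pred, targ, cfg0)
  expect_equal(l0$total, l0$bp)
  lb <- 3.125; la <- 0.4
  expect_equal(lb + 0.01 * la, 3.129)
  same <- list(sbp = 120, dbp = 80, abp = matrix(sin(1:50), 1))
  lz <- total_loss(same, same, loss_config())
  expect_equal(lz$total, 0)
})

test_that("differentiable losses agree with the numeric definitions", {
  set.seed(2)
  B <- 4L; L <- 32L
  bp <- matrix(rnorm(B * 2, c(120, 80), 10), B, 2, byrow = FALSE)
  abp <- array(rnorm(B * L), c(1, B, L))
  targ <- list(sbp = rnorm(B, 120, 5), dbp = rnorm(B, 80, 5),
               abp = matrix(rnorm(B * L), B))
  w <- runif(B, 0.5, 1.5)
  pred_nodes <- list(bp = ag_param(bp), abp = ag_param(abp))
  cfg <- loss_config()
  ln <- radarbp:::total_loss_node(pred_nodes, targ, cfg, w)
  lnum <- total_loss(list(sbp = bp[, 1], dbp = bp[, 2], abp = abp[1, , ]),
                     targ, cfg, w)
  expect_equal(ag_val(ln$total), lnum$total, tolerance = 1e-10)
  # gradient spot check against finite differences
  ag_backward(ln$total)
  g <- pred_nodes$bp$grad
  eps <- 1e-5
  bp2 <- bp; bp2[2, 1] <- bp2[2, 1] + eps
  l2 <- total_loss(list(sbp = bp2[, 1], dbp = bp2[, 2], abp = abp[1, , ]),
                   targ, cfg, w)
  expect_lt(abs((l2$total - lnum$total) / eps - g[2, 1]), 1e-4)
})
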
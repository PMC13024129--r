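test_that("derivative channels follow calculus and are L2-normalized", {
  fs <- 100
  L <- 500L
  ramp <- seq(0, 1, length.out = L)
  X <- derivative_channels(ramp, fs)
  v <- X[2, 2:(L - 1)]
  expect_lt(diff(range(v)), 1e-9)                       # constant velocity
  a_raw <- (ramp[3:L] - 2 * ramp[2:(L - 1)] + ramp[1:(L - 2)]) * fs^2
  expect_lt(max(abs(a_raw)), 1e-6)                      # zero acceleration (raw)
  t <- (seq_len(L) - 1) / fs
  s <- sin(2 * pi * 1.2 * t)
  Xs <- derivative_channels(s, fs)
  # before normalization the velocity is 2 pi f cos(...) within 1%
  v_raw <- numeric(L)
  v_raw[2:(L - 1)] <- (s[3:L] - s[1:(L - 2)]) * fs / 2
  ref <- 2 * pi * 1.2 * cos(2 * pi * 1.2 * t)
  expect_lt(max(abs(v_raw[2:(L - 1)] - ref[2:(L - 1)])) / max(abs(ref)), 0.01)
  for (i in 1:3) expect_lt(abs(sqrt(sum(Xs[i, ]^2)) - 1), 1e-5)
  Z <- derivative_channels(numeric(L), fs)
  expect_true(all(Z == 0))
})

test_that("residual blocks reduce to their shortcut when the branch is zeroed", {
  set.seed(1)
  zero_block <- function(bl) {
    for (p in nn_params(bl)) p$value[] <- 0
    # batch-norm gammas were zeroed too; the residual branch output is then 0
    bl
  }
  bl <- zero_block(nn_resblock(4L, 4L))
  x <- array(rnorm(4 * 2 * 16), c(4, 2, 16))
  expect_equal(ag_val(bl$fwd(ag_node(x))), x)           # identity shortcut
  blp <- nn_resblock(4L, 6L)
  for (nm in c("conv1", "bn1", "conv2", "bn2")) {
    for (p in nn_params(blp$sub[[nm]])) p$value[] <- 0
  }
  proj <- ag_val(blp$sub$proj$fwd(ag_node(x)))
  expect_equal(ag_val(blp$fwd(ag_node(x))), proj)       # 1x1 projection shortcut
  out <- nn_resblock(3L, 8L)$fwd(ag_node(array(rnorm(3 * 2 * 16), c(3, 2, 16))))
  expect_equal(dim(ag_val(out)), c(8, 2, 16))
})

test_that("channel-temporal attention maps saturate and broadcast correctly", {
  set.seed(2)
  cta <- nn_cta(8L, r = 4L, spatial_k = 7L)
  x <- array(rnorm(8 * 2 * 20), c(8, 2, 20))
  res <- cta$fwd(ag_node(x), return_maps = TRUE)
  Mc <- ag_val(res$Mc); Mt <- ag_val(res$Mt)
  expect_true(all(Mc > 0 & Mc < 1))
  expect_true(all(Mt > 0 & Mt < 1))
  expect_equal(ag_val(res$out),
               x * array(t(Mc), dim(x)) *
                 array(matrix(as.numeric(Mt), 8, 40, byrow = TRUE), dim(x)))
  # drive both attention biases to +infinity: maps -> 1, output -> input
  cta$sub$mlp2$params$b$value[] <- 1e4
  cta$sub$tconv$params$b$value[] <- 1e4
  sat <- cta$fwd(ag_node(x), return_maps = TRUE)
  expect_equal(ag_val(sat$out), x, tolerance = 1e-9)
})

test_that("multi-scale bottleneck preserves length and width", {
  set.seed(3)
  ms <- nn_multiscale(8L)
  x <- array(rnorm(8 * 3 * 24), c(8, 3, 24))
  y <- ag_val(ms$fwd(ag_node(x), training = TRUE))
  expect_equal(dim(y), c(8, 3, 24))
  z <- ag_val(ms$fwd(ag_node(array(0, c(8, 3, 24))), training = FALSE))
  expect_true(all(is.finite(z)))
})

test_that("selective scan matches a brute-force recurrence", {
  set.seed(4)
  for (case in 1:5) {
    B <- sample(1:2, 1); D <- sample(2:4, 1); N <- sample(1:4, 1); Tt <- sample(4:8, 1)
    delta <- array(runif(D * B * Tt, 0.01, 0.5), c(D, B, Tt))
    A <- -matrix(runif(D * N, 0.1, 2), D, N)
    Bs <- array(rnorm(N * B * Tt), c(N, B, Tt))
    Cs <- array(rnorm(N * B * Tt), c(N, B, Tt))
    x <- array(rnorm(D * B * Tt), c(D, B, Tt))
    Dp <- rnorm(D)
    y <- selective_ssm_scan(x, list(delta = delta, A = A, B = Bs, C = Cs, D = Dp))
    # scalar-loop oracle
    yo <- array(0, c(D, B, Tt))
    for (b in 1:B) for (dd in 1:D) {
      h <- numeric(N)
      for (t in 1:Tt) {
        h <- exp(delta[dd, b, t] * A[dd, ]) * h +
          delta[dd, b, t] * Bs[, b, t] * x[dd, b, t]
        yo[dd, b, t] <- sum(Cs[, b, t] * h) + Dp[dd] * x[dd, b, t]
      }
    }
    expect_lt(max(abs(y - yo)), 1e-10)
    expect_identical(attr(y, "scan_steps"), Tt)
  }
  # zero input -> zero output; step counter is linear in T
  z <- selective_ssm_scan(array(0, c(2, 1, 6)),
                          list(delta = array(0.1, c(2, 1, 6)),
                               A = matrix(-1, 2, 2),
                               B = array(1, c(2, 1, 6)), C = array(1, c(2, 1, 6))))
  expect_true(all(z == 0))
  expect_identical(attr(z, "scan_steps"), 6L)
  z2 <- selective_ssm_scan(array(0, c(2, 1, 12)),
                           list(delta = array(0.1, c(2, 1, 12)),
                                A = matrix(-1, 2, 2),
                                B = array(1, c(2, 1, 12)), C = array(1, c(2, 1, 12))))
  expect_identical(attr(z2, "scan_steps"), 12L)
  expect_error(selective_ssm_scan(array(NA_real_, c(1, 1, 2)),
                                  list(delta = array(1, c(1, 1, 2)), A = matrix(-1),
                                       B = array(1, c(1, 1, 2)), C = array(1, c(1, 1, 2)))),
               "non-finite")
})

test_that("bidirectional Mamba reduces to layer-normalized input when fused path is zeroed", {
  set.seed(5)
  bm <- nn_bimamba(8L, d_state = 4L)
  x <- array(rnorm(8 * 2 * 12), c(8, 2, 12))
  bm$sub$fuse$params$W$value[] <- 0
  bm$sub$fuse$params$b$value[] <- 0
  out <- ag_val(bm$fwd(ag_node(x)))
  ln <- nn_layernorm(8L)
  expect_equal(out, ag_val(ln$fwd(ag_node(x))), tolerance = 1e-9)
  expect_equal(dim(out), dim(x))
})

test_that("forward pass honours shape contracts and batch independence", {
  set.seed(6)
  model <- maru_model(model_config("tiny"), rng_seed = 6)
  X <- model_input_batch(matrix(rnorm(3 * 256), 3, 256), 100)
  out <- maru_forward(model, X)
  expect_equal(dim(ag_val(out$bp)), c(3L, 2L))
  expect_equal(dim(ag_val(out$abp)), c(1L, 3L, 256L))
  expect_true(all(is.finite(ag_val(out$bp))))
  # identical windows in one batch give identical outputs (eval mode)
  Xd <- X[, c(1, 1, 2), , drop = FALSE]
  od <- ag_val(maru_forward(model, Xd)$bp)
  expect_equal(od[1, ], od[2, ])
  expect_error(maru_forward(model, X[, , 1:100, drop = FALSE]), "input must be")
  # skip-connection shape algebra holds for other lengths divisible by 16
  for (L in c(64L, 128L)) {
    m2 <- maru_model(model_config("tiny", input_len = L), rng_seed = 1)
    o2 <- maru_forward(m2, model_input_batch(matrix(rnorm(2 * L), 2, L), 100))
    expect_equal(dim(ag_val(o2$abp)), c(1L, 2L, L))
  }
  expect_error(model_config("tiny", input_len = 100L), "divisible by 16")
})

test_that("every trainable parameter receives gradient through the total loss", {
  set.seed(7)
  model <- maru_model(model_config("tiny", input_len = 64L), rng_seed = 7)
  X <- model_input_batch(matrix(rnorm(4 * 64), 4, 64), 100)
  out <- maru_forward(model, X, training = TRUE)
  ls <- total_loss_node(out, list(sbp = c(120, 130, 110, 125), dbp = c(80, 85, 75, 82),
                                  abp = matrix(rnorm(4 * 64), 4)),
                        loss_config())
  params <- radarbp:::maru_collect_params(model)
  ag_zero_grad(params)
  ag_backward(ls$total)
  nz <- vapply(params, function(p) !is.null(p$grad) && any(p$grad != 0), logical(1))
  expect_true(all(nz))
})

test_that("tiny model overfits a single batch far below its initial loss", {
  set.seed(8)
  ds <- make_mapping_dataset(4, 8, rng_seed = 8)       # 32 windows
  X <- model_input_batch(ds$rpw, ds$fs)
  model <- maru_model(model_config("tiny"), rng_seed = 8)
  params <- radarbp:::maru_collect_params(model)
  opt <- optim_adamw(params, lr = 3e-3, weight_decay = 1e-5)
  targ <- list(sbp = ds$sbp, dbp = ds$dbp, abp = ds$abp)
  l0 <- NA_real_
  lcur <- Inf
  for (step in 1:500) {
    out <- maru_forward(model, X, training = TRUE)
    ls <- radarbp:::total_loss_node(out, targ, loss_config())
    lcur <- ag_val(ls$total)
    if (step == 1) l0 <- lcur
    if (lcur < 0.05 * l0) break
    ag_zero_grad(params)
    ag_backward(ls$total)
    opt$step()
  }
  expect_lt(lcur, 0.05 * l0)
})
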
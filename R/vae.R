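# One-dimensional variational autoencoder for unsupervised pulse-wave
# quality assessment: two-stage training with KL warm-up, then four-component
# scoring (reconstruction consistency, latent-space consistency, morphology,
# physiological prior).

#' VAE configuration
#'
#' The full profile uses four convolutional stages with channels
#' 32/64/128/256 (kernel 7, stride 2, batch norm, LeakyReLU slope 0.2, one
#' residual block per stage) and a 64-dimensional latent space; the decoder
#' mirrors the encoder with transposed convolutions and a final Tanh. The
#' tiny profile shrinks widths (4/8/16/32, latent 16) for single-CPU runs
#' while keeping the architecture shape.
#'
#' @param profile `"full"` or `"tiny"`.
#' @param input_len window length in samples.
#' @param channels per-stage channel counts (overrides the profile).
#' @param latent latent dimension.
#' @param kernel encoder/decoder kernel size.
#' @param leaky LeakyReLU negative slope.
#' @export
vae_config <- function(profile = c("full", "tiny"), input_len = 1000L,
                       channels = NULL, latent = NULL, kernel = 7L,
                       leaky = 0.2) {
  profile <- match.arg(profile)
  if (is.null(channels)) channels <- if (profile == "full") c(32L, 64L, 128L, 256L) else c(4L, 8L, 16L, 32L)
  if (is.null(latent)) latent <- if (profile == "full") 64L else 16L
  lens <- Reduce(function(L, .) (L + 2L * ((kernel - 1L) %/% 2L) - kernel) %/% 2L + 1L,
                 seq_along(channels), accumulate = TRUE, init = as.integer(input_len))
  structure(list(profile = profile, input_len = as.integer(input_len),
                 channels = channels, latent = as.integer(latent),
                 kernel = as.integer(kernel), leaky = leaky,
                 stage_lens = lens),
            class = "vae_config")
}

#' Build an untrained VAE quality model
#'
#' @param cfg a [vae_config()].
#' @param rng_seed parameter-initialization seed.
#' @return a `vae_model` list of modules; train with [fit_vae()].
#' @export
build_vae <- function(cfg, rng_seed = 1L) {
  stopifnot(inherits(cfg, "vae_config"))
  local_seed(rng_seed, {
    k <- cfg$kernel
    pad <- (k - 1L) %/% 2L
    ch <- cfg$channels
    lens <- cfg$stage_lens                     # input_len, L1, ..., L4
    ns <- length(ch)
    enc <- list()
    in_ch <- 1L
    for (i in seq_len(ns)) {
      enc[[i]] <- list(conv = nn_conv1d(in_ch, ch[i], k, stride = 2L, pad = pad),
                       bn = nn_batchnorm(ch[i]),
                       res = nn_resblock(ch[i], ch[i], 3L))
      in_ch <- ch[i]
    }
    flat <- ch[ns] * lens[ns + 1L]
    to_latent <- nn_dense(flat, 2L * cfg$latent)
    from_latent <- nn_dense(cfg$latent, flat)
    dec <- list()
    for (i in seq_len(ns)) {
      cin <- if (i == 1L) ch[ns] else ch[ns - i + 1L]
      cout <- if (i == ns) 1L else ch[ns - i]
      target <- lens[ns - i + 1L]
      lin <- lens[ns - i + 2L]
      op <- target - (2L * lin - 1L)
      st <- list(tconv = nn_tconv1d(cin, cout, k, stride = 2L, pad = pad, out_pad = op))
      if (i < ns) {
        st$bn <- nn_batchnorm(cout)
        st$res <- nn_resblock(cout, cout, 3L)
      }
      dec[[i]] <- st
    }
    structure(list(cfg = cfg, enc = enc, to_latent = to_latent,
                   from_latent = from_latent, dec = dec,
                   trained_on = NULL, calibration = NULL, history = NULL),
              class = "vae_model")
  })
}

vae_collect_params <- function(vae) {
  ps <- list()
  for (st in vae$enc) for (m in st) ps <- c(ps, nn_params(m))
  ps <- c(ps, nn_params(vae$to_latent), nn_params(vae$from_latent))
  for (st in vae$dec) for (m in st) ps <- c(ps, nn_params(m))
  ps
}

# x: (1, B, L) array -> list(mu, logvar) ag nodes (B, latent)
vae_encode <- function(vae, x, training = FALSE) {
  h <- if (ag_is(x)) x else ag_node(x)
  for (st in vae$enc) {
    h <- ag_leaky_relu(st$bn$fwd(st$conv$fwd(h, training), training), vae$cfg$leaky)
    h <- st$res$fwd(h, training)
  }
  z2 <- vae$to_latent$fwd(ag_to_features(h), training)
  list(mu = ag_slice_f(z2, 1L, vae$cfg$latent),
       logvar = ag_slice_f(z2, vae$cfg$latent + 1L, 2L * vae$cfg$latent))
}

# z: (B, latent) -> (1, B, L) reconstruction
vae_decode <- function(vae, z, training = FALSE) {
  cfg <- vae$cfg
  ns <- length(cfg$channels)
  h <- vae$from_latent$fwd(if (ag_is(z)) z else ag_node(z), training)
  h <- ag_to_signal(h, cfg$channels[ns], cfg$stage_lens[ns + 1L])
  for (i in seq_along(vae$dec)) {
    st <- vae$dec[[i]]
    h <- st$tconv$fwd(h, training)
    if (!is.null(st$bn)) {
      h <- ag_leaky_relu(st$bn$fwd(h, training), cfg$leaky)
      h <- st$res$fwd(h, training)
    }
  }
  ag_tanh(h)
}

#' VAE training objective
#'
#' `total = rec + beta * kl` where `rec` is the per-sample mean squared
#' reconstruction error `(1/L) ||x_tilde - x_hat||^2` averaged over the
#' batch, and `kl` is the analytic Gaussian KL divergence to the standard
#' normal prior, averaged over the batch.
#'
#' @param x_tilde,x_hat standardized input and reconstruction, `(B, 1, L)`
#'   arrays (vectors are treated as a single window).
#' @param mu,logvar latent Gaussian parameters, `(B, latent)`.
#' @param beta KL weight (non-negative).
#' @return list with `total`, `rec`, `kl`.
#' @export
vae_loss <- function(x_tilde, x_hat, mu, logvar, beta = 1) {
  as_b <- function(v) if (is.null(dim(v))) matrix(v, 1L) else v
  xt <- as_b(ag_val(x_tilde)); xh <- as_b(ag_val(x_hat))
  muv <- as_b(ag_val(mu)); lv <- as_b(ag_val(logvar))
  if (!all(is.finite(xt)) || !all(is.finite(xh)) || !all(is.finite(muv)) ||
      !all(is.finite(lv))) stop("non-finite inputs to vae_loss")
  stopifnot(length(xt) == length(xh), beta >= 0)
  B <- dim(muv)[1]
  rec <- mean((xt - xh)^2)
  kl <- 0.5 * sum(muv^2 + exp(lv) - 1 - lv) / B
  list(total = rec + beta * kl, rec = rec, kl = kl)
}

# differentiable version used inside the training loop
vae_loss_node <- function(x_tilde, x_hat, mu, logvar, beta) {
  B <- dim(ag_val(mu))[1]
  rec <- ag_mean_all(ag_square(ag_sub(x_hat, x_tilde)))
  kl <- ag_smul(ag_sum_all(ag_sadd(ag_sub(ag_add(ag_square(mu), ag_exp(logvar)),
                                          logvar), -1)), 0.5 / B)
  total <- ag_add(rec, ag_smul(kl, beta))
  list(total = total, rec = rec, kl = kl)
}

#' KL warm-up schedule
#' @param epoch 1-based epoch index.
#' @param warmup_epochs warm-up length.
#' @param beta_range `c(start, end)`.
#' @return beta at that epoch: linear from start to end over
#'   `warmup_epochs`, then held.
#' @export
beta_schedule <- function(epoch, warmup_epochs = 30L, beta_range = c(0.01, 0.5)) {
  f <- min(1, (epoch - 1) / (warmup_epochs - 1))
  beta_range[1] + f * (beta_range[2] - beta_range[1])
}

#' Select the pre-screened high-quality subset
#' @param prescreen_scores per-window heuristic scores.
#' @param top_fraction fraction retained for stage-1 training.
#' @return integer indices of the top-ranked windows.
#' @export
prescreen_select <- function(prescreen_scores, top_fraction = 0.35) {
  n1 <- max(1L, round(top_fraction * length(prescreen_scores)))
  order(prescreen_scores, decreasing = TRUE)[seq_len(n1)]
}

#' Fit the VAE quality model with two-stage training
#'
#' Stage 1 trains on the top 35% of windows ranked by the heuristic
#' pre-screening score (learning rate 3e-4); stage 2 fine-tunes on all
#' windows at 1.5e-5. The KL weight is warmed up linearly from 0.01 to 0.5
#' over the first 30 epochs and then held. After training, scoring
#' calibration constants are frozen: the high-quality latent center (mean
#' encoder mean over the stage-1 subset) and the median reconstruction error
#' and latent distance over that subset.
#'
#' @param segments standardized windows, `N x L` matrix.
#' @param prescreen_scores length-`N` heuristic scores (computed with
#'   [prescreen_score()] if missing).
#' @param config a [vae_config()].
#' @param rng_seed seed for initialization, shuffling and latent sampling.
#' @param epochs_stage1,epochs_stage2 epoch counts (defaults 100/60;
#'   reduce for CPU runs).
#' @param lr_stage1,lr_stage2 stage learning rates.
#' @param batch_size minibatch size.
#' @param warmup_epochs KL warm-up length.
#' @param beta_range KL weight range.
#' @param subjects optional per-window subject ids recorded as scorer
#'   provenance (leakage guard input).
#' @param fs sampling rate of the windows, Hz.
#' @param verbose print per-epoch losses.
#' @return a calibrated `vae_model` with `$history` (per-epoch `total`,
#'   `rec`, `kl`, `beta`, `stage`).
#' @export
fit_vae <- function(segments, prescreen_scores = NULL, config = vae_config("tiny"),
                    rng_seed = 1L, epochs_stage1 = 100L, epochs_stage2 = 60L,
                    lr_stage1 = 3e-4, lr_stage2 = 1.5e-5, batch_size = 32L,
                    warmup_epochs = 30L, beta_range = c(0.01, 0.5),
                    subjects = NULL, fs = 100, verbose = FALSE) {
  if (is.null(dim(segments))) segments <- matrix(segments, 1L)
  N <- nrow(segments)
  if (N < 1) stop("empty input: need at least one segment")
  stopifnot(ncol(segments) == config$input_len)
  if (is.null(prescreen_scores)) {
    prescreen_scores <- apply(segments, 1, function(w) prescreen_score(w, fs)$s_p)
  }
  vae <- build_vae(config, rng_seed = rng_seed)
  params <- vae_collect_params(vae)
  idx1 <- prescreen_select(prescreen_scores, 0.35)
  history <- data.frame()
  epoch_global <- 0L
  run_stage <- function(idx, epochs, lr, stage) {
    if (epochs < 1) return(invisible(NULL))
    opt <- optim_adamw(params, lr = lr)
    for (ep in seq_len(epochs)) {
      epoch_global <<- epoch_global + 1L
      beta <- beta_schedule(epoch_global, warmup_epochs, beta_range)
      ord <- sample(idx)
      tot <- rec <- kl <- 0
      nb <- 0L
      for (b0 in seq(1L, length(ord), by = batch_size)) {
        bi <- ord[b0:min(length(ord), b0 + batch_size - 1L)]
        x <- array(0, c(1L, length(bi), config$input_len))
        x[1L, , ] <- segments[bi, , drop = FALSE]
        eo <- vae_encode(vae, x, training = TRUE)
        eps <- matrix(stats::rnorm(length(bi) * config$latent),
                      length(bi), config$latent)
        z <- ag_add(eo$mu, ag_mul(ag_exp(ag_smul(eo$logvar, 0.5)), eps))
        xh <- vae_decode(vae, z, training = TRUE)
        ls <- vae_loss_node(ag_node(x), xh, eo$mu, eo$logvar, beta)
        ag_zero_grad(params)
        ag_backward(ls$total)
        opt$step()
        tot <- tot + ag_val(ls$total); rec <- rec + ag_val(ls$rec)
        kl <- kl + ag_val(ls$kl); nb <- nb + 1L
      }
      history <<- rbind(history, data.frame(
        epoch = epoch_global, stage = stage, beta = beta,
        total = tot / nb, rec = rec / nb, kl = kl / nb))
      if (verbose) message(sprintf("stage %d epoch %3d beta %.3f loss %.4f",
                                   stage, epoch_global, beta, tot / nb))
    }
  }
  local_seed(rng_seed + 1L, {
    run_stage(idx1, epochs_stage1, lr_stage1, 1L)
    run_stage(seq_len(N), epochs_stage2, lr_stage2, 2L)
  })
  vae$history <- history
  vae$trained_on <- unique(subjects)
  vae$stage1_idx <- idx1
  # freeze scoring calibration on the stage-1 (high-quality) subset
  cal_x <- segments[idx1, , drop = FALSE]
  enc <- vae_infer(vae, cal_x)
  vae$calibration <- list(
    hq_center = colMeans(enc$mu),
    median_e = stats::median(enc$err),
    median_d = stats::median(sqrt(colSums((t(enc$mu) - colMeans(enc$mu))^2))))
  vae
}

# forward-pass inference: encoder means, deterministic reconstruction and
# per-window reconstruction error (1/L scaling)
vae_infer <- function(vae, segments, batch_size = 64L) {
  if (is.null(dim(segments))) segments <- matrix(segments, 1L)
  N <- nrow(segments)
  L <- ncol(segments)
  mu <- matrix(0, N, vae$cfg$latent)
  xhat <- matrix(0, N, L)
  for (b0 in seq(1L, N, by = batch_size)) {
    bi <- b0:min(N, b0 + batch_size - 1L)
    x <- array(0, c(1L, length(bi), L))
    x[1L, , ] <- segments[bi, , drop = FALSE]
    eo <- vae_encode(vae, x, training = FALSE)
    xh <- vae_decode(vae, eo$mu, training = FALSE)
    mu[bi, ] <- ag_val(eo$mu)
    xhat[bi, ] <- ag_val(xh)[1L, , ]
  }
  err <- rowMeans((segments - xhat)^2)
  list(mu = mu, xhat = xhat, err = err)
}

#' Four-component quality scores for pulse-wave windows
#'
#' Reconstruction consistency `S_R = exp(-e / median_e)` (monotone
#' decreasing in the reconstruction error, 1 at zero error); latent
#' consistency `S_L = exp(-d / median_d)` with `d` the Euclidean distance of
#' the encoder mean from the frozen high-quality center; morphological
#' plausibility `S_M` (mean of peak-count plausibility, peak preservation in
#' the reconstruction within 3 samples, and second-difference smoothness);
#' physiological prior `S_P` = the heuristic pre-screening score.
#'
#' @param segments standardized windows (`N x L` matrix or a vector).
#' @param vae calibrated `vae_model`.
#' @param fs sampling rate, Hz.
#' @return list with `components` (`N x 4` matrix, columns
#'   `S_R, S_L, S_M, S_P`), `err`, `dist`.
#' @export
component_scores <- function(segments, vae, fs = 100) {
  if (is.null(vae$calibration)) stop("uncalibrated scorer: run fit_vae() first")
  if (is.null(dim(segments))) segments <- matrix(segments, 1L)
  inf <- vae_infer(vae, segments)
  cal <- vae$calibration
  dist <- sqrt(colSums((t(inf$mu) - cal$hq_center)^2))
  S_R <- exp(-inf$err / max(cal$median_e, 1e-12))
  S_L <- exp(-dist / max(cal$median_d, 1e-12))
  N <- nrow(segments)
  L <- ncol(segments)
  dur <- L / fs
  S_M <- numeric(N)
  for (i in seq_len(N)) {
    x <- segments[i, ]
    pk <- find_pulse_peaks(x, fs)
    lo <- dur * 0.66; hi <- dur * 3
    count_s <- if (length(pk) >= lo && length(pk) <= hi) 1 else {
      dev <- if (length(pk) < lo) lo - length(pk) else length(pk) - hi
      max(0, 1 - dev / hi)
    }
    pres_s <- if (length(pk) > 0) {
      pk_h <- find_pulse_peaks(inf$xhat[i, ], fs)
      if (length(pk_h) > 0) mean(vapply(pk, function(p) min(abs(pk_h - p)) <= 3,
                                        logical(1))) else 0
    } else 0
    sm <- sum(x^2)
    smooth_s <- if (sm > 1e-12) 1 - min(1, sum(diff(x, differences = 2)^2) / sm) else 0
    S_M[i] <- mean(c(count_s, pres_s, smooth_s))
  }
  S_P <- apply(segments, 1, function(w) prescreen_score(w, fs)$s_p)
  comp <- cbind(S_R = pmin(1, pmax(0, S_R)), S_L = pmin(1, pmax(0, S_L)),
                S_M = pmin(1, pmax(0, S_M)), S_P = pmin(1, pmax(0, S_P)))
  list(components = comp, err = inf$err, dist = dist)
}

#' Serialize / restore a fitted VAE quality model
#' @param vae a `vae_model`.
#' @param path file path.
#' @export
save_vae <- function(vae, path) {
  obj <- list(cfg = vae$cfg, state = vae_model_state(vae),
              trained_on = vae$trained_on, calibration = vae$calibration,
              history = vae$history)
  saveRDS(obj, path, version = 3)
  invisible(path)
}

#' @rdname save_vae
#' @export
load_vae <- function(path) {
  obj <- readRDS(path)
  vae <- build_vae(obj$cfg, rng_seed = 0L)
  vae_model_load_state(vae, obj$state)
  vae$trained_on <- obj$trained_on
  vae$calibration <- obj$calibration
  vae$history <- obj$history
  vae
}

vae_modules <- function(vae) {
  ms <- list()
  for (st in vae$enc) ms <- c(ms, unname(st))
  ms <- c(ms, list(vae$to_latent, vae$from_latent))
  for (st in vae$dec) ms <- c(ms, unname(st))
  ms
}

vae_model_state <- function(vae) lapply(vae_modules(vae), nn_state)

vae_model_load_state <- function(vae, state) {
  ms <- vae_modules(vae)
  stopifnot(length(ms) == length(state))
  for (i in seq_along(ms)) nn_load_state(ms[[i]], state[[i]])
  invisible(vae)
}
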
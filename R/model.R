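# MARU-MTL: residual U-Net encoder, multi-scale channel-temporal attention
# bottleneck, bidirectional Mamba sequence block, attention-gated decoder and
# dual heads (SBP/DBP regression + arterial-waveform reconstruction).

#' MARU-MTL model configuration
#'
#' The full profile is the reference layout: five encoder stages with
#' 1/2/2/2/1 residual blocks and channels 64/128/256/512/1024 (input length
#' divisible by 16; four stride-2 downsampling steps so the bottleneck width
#' is 1024 at 1/16 the input length), CTA reduction 4 with spatial kernel 7,
#' Mamba dimensions d_state 16 / d_conv 4 / expand 2, dropout 0.1, regression
#' head 64-32-2 and waveform head 64-32-16-1. The tiny profile shrinks
#' `base_width` to 4 and the input to 256 samples so the whole network trains
#' on a single CPU.
#'
#' Predictions are produced as `center + scale * head` with fixed anchoring
#' constants chosen from the population pressure range, so the network
#' regresses on an O(1) scale while losses stay in mmHg.
#'
#' @param profile `"full"` or `"tiny"`.
#' @param base_width first-stage channel count.
#' @param input_len window length (divisible by 16).
#' @param blocks residual blocks per encoder stage.
#' @param cta_reduction,cta_spatial_kernel CTA hyperparameters.
#' @param d_state,d_conv,expand Mamba hyperparameters.
#' @param dropout dropout rate in bottleneck and regression head.
#' @param head_hidden hidden width of the regression head.
#' @param abp_channels channel ladder of the waveform head.
#' @param out_center,out_scale output anchoring (SBP, DBP), mmHg.
#' @param bottleneck_variant bottleneck ablation: multi-scale with CTA
#'   (default), multi-scale without CTA, or a single-scale convolution.
#' @param temporal_module `"bimamba"` (default) or `"none"` (ablation).
#' @export
model_config <- function(profile = c("tiny", "full"), base_width = NULL,
                         input_len = NULL, blocks = c(1L, 2L, 2L, 2L, 1L),
                         cta_reduction = 4L, cta_spatial_kernel = 7L,
                         d_state = 16L, d_conv = 4L, expand = 2L,
                         dropout = 0.1, head_hidden = 32L,
                         abp_channels = c(32L, 16L),
                         out_center = c(130, 77.5), out_scale = c(20, 13),
                         bottleneck_variant = c("multiscale_cta", "multiscale",
                                                "single"),
                         temporal_module = c("bimamba", "none")) {
  profile <- match.arg(profile)
  bottleneck_variant <- match.arg(bottleneck_variant)
  temporal_module <- match.arg(temporal_module)
  if (is.null(base_width)) base_width <- if (profile == "full") 64L else 4L
  if (is.null(input_len)) input_len <- if (profile == "full") 1024L else 256L
  if (input_len %% 16L != 0L) stop("input_len must be divisible by 16")
  channels <- as.integer(base_width * c(1L, 2L, 4L, 8L, 16L))
  stopifnot(all(diff(channels) > 0), channels[1] %% 1L == 0L)
  structure(list(profile = profile, base_width = as.integer(base_width),
                 input_len = as.integer(input_len), blocks = as.integer(blocks),
                 channels = channels, cta_reduction = as.integer(cta_reduction),
                 cta_spatial_kernel = as.integer(cta_spatial_kernel),
                 d_state = as.integer(d_state), d_conv = as.integer(d_conv),
                 expand = as.integer(expand), dropout = dropout,
                 head_hidden = as.integer(head_hidden),
                 abp_channels = as.integer(abp_channels),
                 out_center = out_center, out_scale = out_scale,
                 bottleneck_variant = bottleneck_variant,
                 temporal_module = temporal_module),
            class = "maru_config")
}

#' Build the three-channel model input from a pulse wave
#'
#' Channel 1 is the radar pulse wave, channel 2 its first derivative
#' (velocity) and channel 3 its second derivative (acceleration), computed
#' with central differences scaled by the sampling rate (one-sided at the
#' boundaries). Each channel is then L2-normalized over time; an all-zero
#' channel is left at zero.
#'
#' @param rpw numeric window (length at least 3).
#' @param fs sampling rate, Hz.
#' @return `3 x L` matrix with rows RPW, VRPW, ARPW.
#' @export
derivative_channels <- function(rpw, fs = 100) {
  L <- length(rpw)
  stopifnot(L >= 3)
  v <- numeric(L)
  v[2:(L - 1)] <- (rpw[3:L] - rpw[1:(L - 2)]) * fs / 2
  v[1] <- (rpw[2] - rpw[1]) * fs
  v[L] <- (rpw[L] - rpw[L - 1]) * fs
  a <- numeric(L)
  a[2:(L - 1)] <- (rpw[3:L] - 2 * rpw[2:(L - 1)] + rpw[1:(L - 2)]) * fs^2
  a[1] <- a[2]
  a[L] <- a[L - 1]
  X <- rbind(rpw, v, a)
  rownames(X) <- c("rpw", "vrpw", "arpw")
  nrm <- sqrt(rowSums(X^2))
  for (i in 1:3) if (nrm[i] > 0) X[i, ] <- X[i, ] / nrm[i]
  X
}

#' Assemble a batch of model inputs
#' @param rpw_matrix `N x L` matrix of pulse-wave windows.
#' @param fs sampling rate, Hz.
#' @return array `(3, N, L)` of L2-normalized derivative channels.
#' @export
model_input_batch <- function(rpw_matrix, fs = 100) {
  if (is.null(dim(rpw_matrix))) rpw_matrix <- matrix(rpw_matrix, 1L)
  N <- nrow(rpw_matrix)
  L <- ncol(rpw_matrix)
  X <- array(0, c(3L, N, L))
  for (i in seq_len(N)) X[, i, ] <- derivative_channels(rpw_matrix[i, ], fs)
  X
}

#' Build an untrained MARU-MTL model
#'
#' @param cfg a [model_config()].
#' @param rng_seed parameter-initialization seed.
#' @return a `maru_model`; run with [maru_forward()] or [maru_predict()],
#'   train with [train_model()].
#' @export
maru_model <- function(cfg = model_config("tiny"), rng_seed = 1L) {
  stopifnot(inherits(cfg, "maru_config"))
  local_seed(rng_seed, {
    ch <- cfg$channels
    r <- cfg$cta_reduction
    sk <- cfg$cta_spatial_kernel
    enc <- list()
    in_ch <- 3L
    for (i in 1:5) {
      blocks <- list()
      bin <- in_ch
      for (bidx in seq_len(cfg$blocks[i])) {
        blocks[[bidx]] <- nn_resblock(bin, ch[i])
        bin <- ch[i]
      }
      st <- list(blocks = blocks)
      if (i < 5L) st$down <- nn_conv1d(ch[i], ch[i], 3L, stride = 2L, pad = 1L)
      enc[[i]] <- st
      in_ch <- ch[i]
    }
    bottleneck <- switch(cfg$bottleneck_variant,
      multiscale_cta = nn_multiscale(ch[5], r, sk, use_cta = TRUE),
      multiscale = nn_multiscale(ch[5], r, sk, use_cta = FALSE),
      single = {
        conv <- nn_conv1d(ch[5], ch[5], 3L)
        bn <- nn_batchnorm(ch[5])
        new_module(sub = list(conv = conv, bn = bn),
                   fwd = function(x, training = FALSE)
                     ag_relu(bn$fwd(conv$fwd(x, training), training)))
      })
    bim <- if (cfg$temporal_module == "bimamba") {
      nn_bimamba(ch[5], cfg$d_state, cfg$d_conv, cfg$expand)
    } else {
      new_module(fwd = function(x, training = FALSE) x)
    }
    dec <- list()
    prev <- ch[5]
    for (j in 4:1) {
      dec[[5 - j]] <- list(cta = nn_cta(ch[j], r, sk),
                           res = nn_resblock(prev + ch[j], ch[j]))
      prev <- ch[j]
    }
    fc1 <- nn_dense(ch[1], cfg$head_hidden)
    fc2 <- nn_dense(cfg$head_hidden, 2L)
    ab <- cfg$abp_channels
    abp1 <- nn_conv1d(ch[1], ab[1], 3L)
    abp2 <- nn_conv1d(ab[1], ab[2], 3L)
    abp3 <- nn_conv1d(ab[2], 1L, 1L)
    structure(list(cfg = cfg, enc = enc, bottleneck = bottleneck, bimamba = bim,
                   dec = dec, fc1 = fc1, fc2 = fc2,
                   abp_head = list(abp1 = abp1, abp2 = abp2, abp3 = abp3),
                   trained_on = NULL),
              class = "maru_model")
  })
}

maru_collect_params <- function(model) {
  ps <- list()
  for (st in model$enc) {
    for (bl in st$blocks) ps <- c(ps, nn_params(bl))
    if (!is.null(st$down)) ps <- c(ps, nn_params(st$down))
  }
  ps <- c(ps, nn_params(model$bottleneck), nn_params(model$bimamba))
  for (st in model$dec) ps <- c(ps, nn_params(st$cta), nn_params(st$res))
  ps <- c(ps, nn_params(model$fc1), nn_params(model$fc2))
  for (m in model$abp_head) ps <- c(ps, nn_params(m))
  ps
}

maru_modules <- function(model) {
  ms <- list()
  for (st in model$enc) {
    ms <- c(ms, st$blocks)
    if (!is.null(st$down)) ms <- c(ms, list(st$down))
  }
  ms <- c(ms, list(model$bottleneck, model$bimamba))
  for (st in model$dec) ms <- c(ms, list(st$cta, st$res))
  c(ms, list(model$fc1, model$fc2), unname(model$abp_head))
}

#' Run the network on a batch of inputs
#'
#' Encoder (five stages, stride-2 downsampling after the first four),
#' multi-scale CTA bottleneck, bidirectional Mamba with dropout, decoder
#' (four up-stages with linear-interpolation upsampling and CTA-refined skip
#' concatenation), then the two heads: global average pooling with two fully
#' connected layers for (SBP, DBP), and three convolutions plus
#' interpolation for the arterial waveform.
#'
#' @param model a `maru_model`.
#' @param X input array `(3, B, L)` from [model_input_batch()].
#' @param training enable batch-norm batch statistics and dropout.
#' @return list with `bp` (`(B, 2)` node, mmHg), `abp` (`(1, B, L)` node).
#' @export
maru_forward <- function(model, X, training = FALSE) {
  cfg <- model$cfg
  d <- dim(ag_val(X))
  if (d[1] != 3L || d[3] != cfg$input_len) {
    stop("input must be (3, B, ", cfg$input_len, "); got (",
         paste(d, collapse = ", "), ")")
  }
  h <- if (ag_is(X)) X else ag_node(X)
  skips <- list()
  for (i in 1:5) {
    st <- model$enc[[i]]
    for (bl in st$blocks) h <- bl$fwd(h, training)
    if (i < 5L) {
      skips[[i]] <- h
      h <- st$down$fwd(h, training)
    }
  }
  h <- model$bottleneck$fwd(h, training)
  h <- model$bimamba$fwd(h, training)
  h <- ag_dropout(h, cfg$dropout, training)
  for (j in 4:1) {
    st <- model$dec[[5 - j]]
    skip <- skips[[j]]
    h <- ag_upsample_linear(h, dim(ag_val(skip))[3])
    h <- ag_concat_c(list(h, st$cta$fwd(skip, training)))
    h <- st$res$fwd(h, training)
  }
  d1 <- h
  g <- ag_gap(d1)
  hid <- ag_dropout(ag_relu(model$fc1$fwd(g, training)), cfg$dropout, training)
  raw <- model$fc2$fwd(hid, training)
  ctr <- matrix(cfg$out_center, dim(ag_val(raw))[1], 2L, byrow = TRUE)
  scl <- matrix(cfg$out_scale, dim(ag_val(raw))[1], 2L, byrow = TRUE)
  bp <- ag_add(ag_mul(raw, scl), ctr)
  ah <- model$abp_head
  w <- ag_relu(ah$abp1$fwd(d1, training))
  w <- ag_relu(ah$abp2$fwd(w, training))
  w <- ah$abp3$fwd(w, training)
  if (dim(ag_val(w))[3] != cfg$input_len) w <- ag_upsample_linear(w, cfg$input_len)
  list(bp = bp, abp = w)
}

#' Predict blood pressure and waveform for pulse-wave windows
#'
#' @param model trained `maru_model`.
#' @param rpw_matrix `N x L` matrix of pulse-wave windows.
#' @param fs sampling rate, Hz.
#' @param batch_size forward batch size.
#' @return list with `sbp`, `dbp` (mmHg vectors) and `abp` (`N x L` matrix,
#'   arbitrary scale).
#' @export
maru_predict <- function(model, rpw_matrix, fs = 100, batch_size = 64L) {
  if (is.null(dim(rpw_matrix))) rpw_matrix <- matrix(rpw_matrix, 1L)
  N <- nrow(rpw_matrix)
  L <- ncol(rpw_matrix)
  sbp <- dbp <- numeric(N)
  abp <- matrix(0, N, L)
  for (b0 in seq(1L, N, by = batch_size)) {
    bi <- b0:min(N, b0 + batch_size - 1L)
    X <- model_input_batch(rpw_matrix[bi, , drop = FALSE], fs)
    out <- maru_forward(model, X, training = FALSE)
    bp <- ag_val(out$bp)
    sbp[bi] <- bp[, 1]
    dbp[bi] <- bp[, 2]
    abp[bi, ] <- ag_val(out$abp)[1L, , ]
  }
  list(sbp = sbp, dbp = dbp, abp = abp)
}

#' Serialize / restore a MARU-MTL model
#' @param model a `maru_model`.
#' @param path file path.
#' @export
save_model <- function(model, path) {
  saveRDS(list(cfg = model$cfg, state = lapply(maru_modules(model), nn_state),
               trained_on = model$trained_on),
          path, version = 3)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  model <- maru_model(obj$cfg, rng_seed = 0L)
  ms <- maru_modules(model)
  stopifnot(length(ms) == length(obj$state))
  for (i in seq_along(ms)) nn_load_state(ms[[i]], obj$state[[i]])
  model$trained_on <- obj$trained_on
  model
}
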
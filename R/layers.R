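# Neural layer constructors on top of the autodiff engine.
#
# A module is a plain list with fields:
#   $params : named list of ag parameter nodes
#   $sub    : named list of child modules
#   $fwd    : function(x, training = FALSE) -> ag node
# Parameter initialization draws from the current R RNG stream, so callers
# control determinism with set.seed().

new_module <- function(params = list(), sub = list(), fwd = NULL, ...) {
  structure(list(params = params, sub = sub, fwd = fwd, ...),
            class = "nn_module")
}

#' Collect all trainable parameters of a module tree
#' @param m a module built by the `nn_*` constructors.
#' @return flat list of `ag` parameter nodes, in a stable order.
#' @export
nn_params <- function(m) {
  out <- unname(m$params)
  for (s in m$sub) out <- c(out, nn_params(s))
  out
}

#' Extract / restore parameter and batch-norm state as plain arrays
#' @param m module.
#' @return list with `params` (arrays) and `bn` (running-stat list).
#' @export
nn_state <- function(m) {
  list(params = lapply(nn_params(m), function(p) p$value),
       bn = lapply(nn_bn_states(m), function(e) list(mean = e$running_mean,
                                                     var = e$running_var)))
}

#' @rdname nn_state
#' @param state a list previously produced by [nn_state()].
#' @export
nn_load_state <- function(m, state) {
  ps <- nn_params(m)
  stopifnot(length(ps) == length(state$params))
  for (i in seq_along(ps)) ps[[i]]$value <- state$params[[i]]
  bs <- nn_bn_states(m)
  stopifnot(length(bs) == length(state$bn))
  for (i in seq_along(bs)) {
    bs[[i]]$running_mean <- state$bn[[i]]$mean
    bs[[i]]$running_var <- state$bn[[i]]$var
  }
  invisible(m)
}

nn_bn_states <- function(m) {
  out <- list()
  if (!is.null(m$bn_state)) out <- list(m$bn_state)
  for (s in m$sub) out <- c(out, nn_bn_states(s))
  out
}

n_parameters <- function(m) sum(vapply(nn_params(m), function(p) length(p$value), numeric(1)))

rand_arr <- function(dims, sd) array(stats::rnorm(prod(dims), sd = sd), dims)

#' 1-D convolution layer
#' @param in_ch,out_ch channel counts.
#' @param k kernel size; `pad` defaults to same-padding for stride 1.
#' @param stride,pad,bias usual convolution options.
#' @export
nn_conv1d <- function(in_ch, out_ch, k, stride = 1L, pad = (k - 1L) %/% 2L, bias = TRUE) {
  force(stride); force(pad)
  W <- ag_param(rand_arr(c(out_ch, in_ch, k), sd = sqrt(2 / (in_ch * k))))
  b <- if (bias) ag_param(numeric(out_ch)) else NULL
  params <- if (bias) list(W = W, b = b) else list(W = W)
  new_module(params = params,
             fwd = function(x, training = FALSE) ag_conv1d(x, W, b, stride = stride, pad = pad),
             in_ch = in_ch, out_ch = out_ch, k = k, stride = stride, pad = pad)
}

#' Transposed 1-D convolution (zero-insertion upsampling followed by a
#' stride-1 convolution with the flipped kernel)
#' @inheritParams nn_conv1d
#' @param out_pad extra right-side samples to hit odd target lengths.
#' @export
nn_tconv1d <- function(in_ch, out_ch, k, stride = 2L, pad = (k - 1L) %/% 2L,
                       out_pad = 0L, bias = TRUE) {
  force(stride); force(pad); force(out_pad)
  W <- ag_param(rand_arr(c(out_ch, in_ch, k), sd = sqrt(2 / (in_ch * k))))
  b <- if (bias) ag_param(numeric(out_ch)) else NULL
  params <- if (bias) list(W = W, b = b) else list(W = W)
  fwd <- function(x, training = FALSE) {
    xs <- ag_zero_stuff(x, stride)
    xs <- ag_pad_l(xs, left = k - 1L - pad, right = k - 1L - pad + out_pad)
    # flip kernel along its tap axis so the op is a true deconvolution
    Wf <- ag_node(W$value[, , dim(W$value)[3]:1, drop = FALSE], parents = list(W))
    Wf$backward <- function(g) ag_accum(W, g[, , dim(g)[3]:1, drop = FALSE])
    ag_conv1d(xs, Wf, b, stride = 1L, pad = 0L)
  }
  new_module(params = params, fwd = fwd)
}

#' Fully connected layer
#' @param fin,fout input/output widths.
#' @export
nn_dense <- function(fin, fout, bias = TRUE) {
  W <- ag_param(rand_arr(c(fin, fout), sd = sqrt(2 / fin)))
  b <- if (bias) ag_param(numeric(fout)) else NULL
  params <- if (bias) list(W = W, b = b) else list(W = W)
  new_module(params = params,
             fwd = function(x, training = FALSE) ag_dense(x, W, b))
}

#' Batch normalization over (batch, length) per channel
#' @param C channel count.
#' @export
nn_batchnorm <- function(C) {
  gamma <- ag_param(rep(1, C))
  beta <- ag_param(numeric(C))
  st <- new.env(parent = emptyenv())
  st$running_mean <- numeric(C)
  st$running_var <- rep(1, C)
  new_module(params = list(gamma = gamma, beta = beta),
             fwd = function(x, training = FALSE)
               ag_batchnorm(x, gamma, beta, st, training = training),
             bn_state = st)
}

#' Layer normalization over the channel axis
#' @param C channel count.
#' @export
nn_layernorm <- function(C) {
  gamma <- ag_param(rep(1, C))
  beta <- ag_param(numeric(C))
  new_module(params = list(gamma = gamma, beta = beta),
             fwd = function(x, training = FALSE) ag_layernorm_c(x, gamma, beta))
}

#' Residual block: two conv-BN stages with identity or projection shortcut
#'
#' Implements `y = F(x) + shortcut(x)` where `F` is
#' conv(k)-BN-ReLU-conv(k)-BN; a 1x1 projection convolution is used on the
#' shortcut when the channel counts differ.
#'
#' @param in_ch,out_ch channel counts.
#' @param k kernel size of the two main convolutions.
#' @export
nn_resblock <- function(in_ch, out_ch, k = 3L) {
  conv1 <- nn_conv1d(in_ch, out_ch, k)
  bn1 <- nn_batchnorm(out_ch)
  conv2 <- nn_conv1d(out_ch, out_ch, k)
  bn2 <- nn_batchnorm(out_ch)
  proj <- if (in_ch != out_ch) nn_conv1d(in_ch, out_ch, 1L) else NULL
  sub <- list(conv1 = conv1, bn1 = bn1, conv2 = conv2, bn2 = bn2)
  if (!is.null(proj)) sub$proj <- proj
  fwd <- function(x, training = FALSE) {
    h <- ag_relu(bn1$fwd(conv1$fwd(x, training), training))
    h <- bn2$fwd(conv2$fwd(h, training), training)
    sc <- if (is.null(proj)) x else proj$fwd(x, training)
    ag_add(h, sc)
  }
  new_module(sub = sub, fwd = fwd)
}

#' Channel-temporal attention (CTA) module
#'
#' The channel map pools the feature map globally over time (average and max),
#' passes both descriptors through a shared bottleneck perceptron with
#' reduction `r`, and applies a sigmoid to their sum. The temporal map stacks
#' channel-wise average/max pooling and applies a kernel-`spatial_k`
#' convolution plus sigmoid. The input is recalibrated by both maps:
#' `F' = F (*) Mc (*) Mt`.
#'
#' @param C channel count (must be at least `r`).
#' @param r channel reduction ratio of the shared perceptron.
#' @param spatial_k kernel size of the temporal-attention convolution.
#' @export
nn_cta <- function(C, r = 4L, spatial_k = 7L) {
  stopifnot(C >= r)
  mlp1 <- nn_dense(C, max(1L, C %/% r))
  mlp2 <- nn_dense(max(1L, C %/% r), C)
  tconv <- nn_conv1d(2L, 1L, spatial_k)
  fwd <- function(x, training = FALSE, return_maps = FALSE) {
    avg <- ag_gap(x)
    mx <- ag_gmp(x)
    mlp <- function(v) mlp2$fwd(ag_relu(mlp1$fwd(v, training)), training)
    Mc <- ag_sigmoid(ag_add(mlp(avg), mlp(mx)))
    tstack <- ag_concat_c(list(ag_cmean(x), ag_cmax(x)))
    Mt <- ag_sigmoid(tconv$fwd(tstack, training))
    out <- ag_mul_tmap(ag_mul_cmap(x, Mc), Mt)
    if (return_maps) list(out = out, Mc = Mc, Mt = Mt) else out
  }
  new_module(sub = list(mlp1 = mlp1, mlp2 = mlp2, tconv = tconv), fwd = fwd)
}

#' Multi-scale attention bottleneck
#'
#' Three parallel convolution branches (kernel sizes 1, 3, 5), each followed by
#' batch normalization, ReLU and CTA refinement; branch outputs are
#' concatenated along channels and fused by a pointwise convolution with batch
#' normalization and ReLU back to the bottleneck width.
#'
#' @param C bottleneck channel count.
#' @param r,spatial_k CTA hyperparameters.
#' @param use_cta disable CTA refinement of the branches (ablation variant).
#' @export
nn_multiscale <- function(C, r = 4L, spatial_k = 7L, use_cta = TRUE) {
  branches <- lapply(c(1L, 3L, 5L), function(k) {
    br <- list(conv = nn_conv1d(C, C, k), bn = nn_batchnorm(C))
    if (use_cta) br$cta <- nn_cta(C, r, spatial_k)
    br
  })
  fuse <- nn_conv1d(3L * C, C, 1L)
  fbn <- nn_batchnorm(C)
  sub <- list(fuse = fuse, fbn = fbn)
  for (i in 1:3) for (nm in names(branches[[i]])) {
    sub[[paste0("b", i, nm)]] <- branches[[i]][[nm]]
  }
  fwd <- function(x, training = FALSE) {
    zs <- lapply(branches, function(br) {
      z <- ag_relu(br$bn$fwd(br$conv$fwd(x, training), training))
      if (use_cta) br$cta$fwd(z, training) else z
    })
    ag_relu(fbn$fwd(fuse$fwd(ag_concat_c(zs), training), training))
  }
  new_module(sub = sub, fwd = fwd)
}

#' Mamba (selective state-space) block
#'
#' Canonical selective-SSM formulation: input projection to an expanded width,
#' depthwise causal convolution with SiLU, input-dependent step sizes via a
#' low-rank projection and softplus, zero-order-hold discretization of a
#' diagonal state matrix with S4D-real initialization, a linear-time scan, SiLU
#' gating, and an output projection.
#'
#' @param d_model model width at the bottleneck.
#' @param d_state state dimension `N` per channel.
#' @param d_conv depthwise convolution width.
#' @param expand expansion factor for the inner width.
#' @param dt_rank rank of the step-size projection.
#' @export
nn_mamba <- function(d_model, d_state = 16L, d_conv = 4L, expand = 2L,
                     dt_rank = max(1L, d_model %/% 16L)) {
  d_inner <- expand * d_model
  in_proj <- nn_conv1d(d_model, 2L * d_inner, 1L, bias = FALSE)
  dw <- ag_param(rand_arr(c(d_inner, d_conv), sd = sqrt(1 / d_conv)))
  dwb <- ag_param(numeric(d_inner))
  x_proj <- nn_conv1d(d_inner, dt_rank + 2L * d_state, 1L, bias = FALSE)
  dt_proj <- nn_conv1d(dt_rank, d_inner, 1L, bias = TRUE)
  # softplus(bias) spread log-uniformly over [1e-3, 1e-1]
  dt_init <- exp(stats::runif(d_inner, log(1e-3), log(1e-1)))
  dt_proj$params$b$value <- log(expm1(dt_init))
  A_log <- ag_param(matrix(log(seq_len(d_state)), d_inner, d_state, byrow = TRUE))
  Dp <- ag_param(rep(1, d_inner))
  out_proj <- nn_conv1d(d_inner, d_model, 1L, bias = FALSE)
  sub <- list(in_proj = in_proj, x_proj = x_proj, dt_proj = dt_proj, out_proj = out_proj)
  fwd <- function(x, training = FALSE) {
    xz <- in_proj$fwd(x, training)
    xin <- ag_slice_c(xz, 1L, d_inner)
    z <- ag_slice_c(xz, d_inner + 1L, 2L * d_inner)
    xc <- ag_silu(ag_dwconv_causal(xin, dw, dwb))
    pr <- x_proj$fwd(xc, training)
    dt <- ag_softplus(dt_proj$fwd(ag_slice_c(pr, 1L, dt_rank), training))
    Bs <- ag_slice_c(pr, dt_rank + 1L, dt_rank + d_state)
    Cs <- ag_slice_c(pr, dt_rank + d_state + 1L, dt_rank + 2L * d_state)
    A <- ag_neg(ag_exp(A_log))
    y <- ag_selective_scan(dt, A, Bs, Cs, xc, Dp)
    y <- ag_mul(y, ag_silu(z))
    out_proj$fwd(y, training)
  }
  new_module(params = list(dw = dw, dwb = dwb, A_log = A_log, Dp = Dp),
             sub = sub, fwd = fwd, d_model = d_model)
}

#' Bidirectional Mamba block
#'
#' Runs two independent Mamba branches over the sequence and its time
#' reversal, concatenates the branch outputs, fuses them with a linear
#' (pointwise) projection plus GELU, and applies a residual connection
#' followed by layer normalization:
#' `h_out = LN(GELU(Linear([h_f; h_b])) + F_ms)`.
#'
#' @inheritParams nn_mamba
#' @export
nn_bimamba <- function(d_model, d_state = 16L, d_conv = 4L, expand = 2L,
                       dt_rank = max(1L, d_model %/% 16L)) {
  fwd_br <- nn_mamba(d_model, d_state, d_conv, expand, dt_rank)
  bwd_br <- nn_mamba(d_model, d_state, d_conv, expand, dt_rank)
  fuse <- nn_conv1d(2L * d_model, d_model, 1L)
  ln <- nn_layernorm(d_model)
  fwd <- function(x, training = FALSE, return_prefuse = FALSE) {
    hf <- fwd_br$fwd(x, training)
    hb <- ag_flip_l(bwd_br$fwd(ag_flip_l(x), training))
    cat_fb <- ag_concat_c(list(hf, hb))
    fused <- ag_gelu(fuse$fwd(cat_fb, training))
    out <- ln$fwd(ag_add(fused, x), training)
    if (return_prefuse) list(out = out, fused = fused, hf = hf, hb = hb) else out
  }
  new_module(sub = list(fwd_br = fwd_br, bwd_br = bwd_br, fuse = fuse, ln = ln),
             fwd = fwd)
}

#' Selective state-space scan on plain numeric inputs
#'
#' Functional forward-only interface to the content-aware SSM recurrence
#' `h_t = exp(delta_t A) h_{t-1} + delta_t B_t x_t`, `y_t = C_t h_t + D x_t`.
#' Useful for inspecting the recurrence itself; model training uses the
#' differentiable version internally.
#'
#' @param x input array `(B, D, T)`.
#' @param params list with `delta (B, D, T)`, `A (D, N)`, `B (B, N, T)`,
#'   `C (B, N, T)` and optionally `D` (length `D`, default 0).
#' @return array `(B, D, T)` with attribute `scan_steps` equal to the number
#'   of recurrence steps (linear in `T`).
#' @export
selective_ssm_scan <- function(x, params) {
  stopifnot(is.array(x), length(dim(x)) == 3L)
  for (nm in c("delta", "A", "B", "C")) {
    if (is.null(params[[nm]])) stop("params$", nm, " missing")
    if (!all(is.finite(params[[nm]]))) stop("non-finite SSM parameters")
  }
  if (!all(is.finite(x))) stop("non-finite SSM input")
  Dp <- params$D %||% numeric(dim(x)[2])
  node <- ag_selective_scan(params$delta, params$A, params$B, params$C, x, Dp)
  node$value
}

# ---- optimizers ---------------------------------------------------------

#' AdamW optimizer with decoupled weight decay
#' @param params list of `ag` parameter nodes.
#' @param lr learning rate.
#' @param weight_decay decoupled weight-decay coefficient.
#' @param betas,eps Adam moment coefficients.
#' @return environment with a `$step(lr)` function.
#' @export
optim_adamw <- function(params, lr = 1e-3, weight_decay = 0, betas = c(0.9, 0.999),
                        eps = 1e-8) {
  st <- new.env(parent = emptyenv())
  st$params <- params
  st$lr <- lr
  st$m <- lapply(params, function(p) array(0, dim(p$value) %||% length(p$value)))
  st$v <- st$m
  st$t <- 0L
  st$step <- function(lr = st$lr) {
    st$t <- st$t + 1L
    b1 <- betas[1]; b2 <- betas[2]
    bc1 <- 1 - b1^st$t
    bc2 <- 1 - b2^st$t
    for (i in seq_along(st$params)) {
      p <- st$params[[i]]
      g <- p$grad
      if (is.null(g)) next
      st$m[[i]] <- b1 * st$m[[i]] + (1 - b1) * g
      st$v[[i]] <- b2 * st$v[[i]] + (1 - b2) * g^2
      mhat <- st$m[[i]] / bc1
      vhat <- st$v[[i]] / bc2
      p$value <- p$value - lr * (mhat / (sqrt(vhat) + eps) + weight_decay * p$value)
    }
    invisible(NULL)
  }
  st
}

#' Cosine-annealing learning-rate schedule
#' @param lr0 initial learning rate.
#' @param t_max total number of epochs.
#' @param lr_min floor learning rate.
#' @return function(epoch) -> learning rate.
#' @export
lr_cosine <- function(lr0, t_max, lr_min = lr0 / 100) {
  function(epoch) lr_min + 0.5 * (lr0 - lr_min) * (1 + cos(pi * (epoch - 1) / max(1, t_max - 1)))
}
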
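# Multi-task training objective: weighted Huber blood-pressure regression
# plus instance-normalized Smooth-L1 arterial-waveform reconstruction.

#' Loss configuration
#'
#' `lambda_sbp` up-weights the systolic term (its numeric range is larger),
#' `lambda_abp` weighs the auxiliary waveform reconstruction, and `delta` is
#' the Huber threshold in mmHg.
#'
#' @param lambda_sbp systolic weight.
#' @param lambda_abp auxiliary-task weight.
#' @param delta Huber quadratic/linear switch point, mmHg.
#' @param use_sample_weights apply per-window quality weights.
#' @export
loss_config <- function(lambda_sbp = 2.0, lambda_abp = 0.01, delta = 1.0,
                        use_sample_weights = TRUE) {
  stopifnot(lambda_sbp >= 0, lambda_abp >= 0, delta >= 0)
  structure(list(lambda_sbp = lambda_sbp, lambda_abp = lambda_abp,
                 delta = delta, use_sample_weights = use_sample_weights),
            class = "loss_config")
}

#' Huber loss
#'
#' `0.5 e^2` for `|e| <= delta`, `delta |e| - 0.5 delta^2` otherwise
#' (continuous at the switch point for every `delta`); the mean is taken
#' over a batch.
#'
#' @param y_hat,y predictions and targets (scalars or vectors).
#' @param delta switch point.
#' @export
huber <- function(y_hat, y, delta = 1) {
  stopifnot(all(is.finite(y_hat)), all(is.finite(y)), delta >= 0)
  e <- abs(y_hat - y)
  mean(ifelse(e <= delta, 0.5 * e^2, delta * e - 0.5 * delta^2))
}

#' Blood-pressure regression loss
#'
#' `lambda_sbp`-weighted systolic Huber plus unweighted diastolic Huber;
#' per-window losses are multiplied by the quality sample weights before the
#' batch mean.
#'
#' @param pred list with `sbp`, `dbp` vectors (mmHg).
#' @param target list with `sbp`, `dbp` vectors (mmHg).
#' @param cfg a [loss_config()].
#' @param sample_weights per-window weights (default 1).
#' @export
bp_loss <- function(pred, target, cfg = loss_config(), sample_weights = NULL) {
  n <- length(pred$sbp)
  if (is.null(sample_weights)) sample_weights <- rep(1, n)
  h <- function(e) ifelse(abs(e) <= cfg$delta, 0.5 * e^2,
                          cfg$delta * abs(e) - 0.5 * cfg$delta^2)
  per <- cfg$lambda_sbp * h(pred$sbp - target$sbp) + h(pred$dbp - target$dbp)
  mean(sample_weights * per)
}

smooth_l1 <- function(d, beta = 1) {
  ifelse(abs(d) <= beta, 0.5 * d^2 / beta, abs(d) - 0.5 * beta)
}

instance_normalize <- function(x, eps = 1e-6) {
  if (is.null(dim(x))) x <- matrix(x, 1L)
  mu <- rowMeans(x)
  sd_ <- sqrt(rowMeans((x - mu)^2))
  (x - mu) / (sd_ + eps)
}

#' Arterial-waveform reconstruction loss
#'
#' Both waveforms are instance-normalized per sample (zero mean, unit
#' variance over time, epsilon-guarded) before a Smooth-L1 comparison
#' averaged over samples and time; the loss is therefore invariant to
#' positive affine rescaling of either waveform.
#'
#' @param pred_wave,target_wave `N x L` matrices (or vectors) of waveforms.
#' @param sample_weights optional per-window weights.
#' @export
abp_recon_loss <- function(pred_wave, target_wave, sample_weights = NULL) {
  p <- instance_normalize(pred_wave)
  t_ <- instance_normalize(target_wave)
  stopifnot(all(dim(p) == dim(t_)))
  per <- rowMeans(smooth_l1(p - t_))
  if (is.null(sample_weights)) mean(per) else mean(sample_weights * per)
}

#' Total multi-task loss
#'
#' `L = L_BP + lambda_abp * L_ABP`, exactly; `lambda_abp = 0` disables the
#' auxiliary path.
#'
#' @param pred list with `sbp`, `dbp`, `abp` (`N x L`).
#' @param target list with `sbp`, `dbp`, `abp`.
#' @param cfg a [loss_config()].
#' @param sample_weights optional per-window quality weights.
#' @return list with `total`, `bp`, `abp`.
#' @export
total_loss <- function(pred, target, cfg = loss_config(), sample_weights = NULL) {
  if (!isTRUE(cfg$use_sample_weights)) sample_weights <- NULL
  lb <- bp_loss(pred, target, cfg, sample_weights)
  la <- if (cfg$lambda_abp > 0) abp_recon_loss(pred$abp, target$abp, sample_weights) else 0
  list(total = lb + cfg$lambda_abp * la, bp = lb, abp = la)
}

# ---- differentiable versions used by the training loop ------------------

# elementwise Huber on an ag node of errors
ag_huber_e <- function(e, delta) {
  ev <- ag_val(e)
  a <- abs(ev)
  quad <- a <= delta
  v <- ifelse(quad, 0.5 * ev^2, delta * a - 0.5 * delta^2)
  out <- ag_node(v, parents = list(e))
  out$backward <- function(g) ag_accum(e, g * pmax(pmin(ev, delta), -delta))
  out
}

# elementwise Smooth-L1 (beta = 1) on an ag node of differences
ag_smooth_l1_d <- function(d) {
  dv <- ag_val(d)
  a <- abs(dv)
  v <- ifelse(a <= 1, 0.5 * dv^2, a - 0.5)
  out <- ag_node(v, parents = list(d))
  out$backward <- function(g) ag_accum(d, g * pmax(pmin(dv, 1), -1))
  out
}

# pred: list(bp (B,2) node, abp (1,B,L) node); targets numeric
total_loss_node <- function(pred, target, cfg, sample_weights = NULL) {
  B <- length(target$sbp)
  w <- if (isTRUE(cfg$use_sample_weights) && !is.null(sample_weights)) {
    sample_weights
  } else rep(1, B)
  tm <- cbind(target$sbp, target$dbp)
  hub <- ag_huber_e(ag_sub(pred$bp, tm), cfg$delta)
  lw <- matrix(c(cfg$lambda_sbp * w, w), B, 2L)
  lb <- ag_smul(ag_sum_all(ag_mul(hub, lw)), 1 / B)
  if (cfg$lambda_abp > 0) {
    ta <- instance_normalize(target$abp)
    ta3 <- array(0, dim(ag_val(pred$abp)))
    ta3[1L, , ] <- ta
    pa <- ag_instnorm_l(pred$abp)
    sl <- ag_smooth_l1_d(ag_sub(pa, ta3))
    L <- dim(ag_val(pred$abp))[3]
    wa <- array(0, dim(ag_val(pred$abp)))
    wa[1L, , ] <- matrix(w, B, L)
    la <- ag_smul(ag_sum_all(ag_mul(sl, wa)), 1 / (B * L))
    total <- ag_add(lb, ag_smul(la, cfg$lambda_abp))
  } else {
    la <- NULL
    total <- lb
  }
  list(total = total, bp = lb, abp = la)
}
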
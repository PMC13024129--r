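# Heuristic pre-screening, quality-score fusion, adaptive thresholding and
# dataset screening for the VAE-based signal quality index.

#' Detect pulse peaks in a standardized window
#' @param x numeric window (standardized scale).
#' @param fs sampling rate, Hz.
#' @return integer vector of peak indices (possibly empty).
#' @export
find_pulse_peaks <- function(x, fs = 100) {
  if (stats::sd(x) < 1e-12) return(integer(0))
  pk <- pracma::findpeaks(x, minpeakdistance = max(2L, round(fs / 3)),
                          minpeakheight = mean(x) + 0.25 * stats::sd(x))
  if (is.null(pk)) integer(0) else sort(pk[, 2])
}

spectral_energy <- function(x, fs) {
  n <- length(x)
  sp <- Mod(stats::fft(x))^2 / n
  fr <- (seq_len(n) - 1) * fs / n
  half <- fr <= fs / 2
  list(power = sp[half], freq = fr[half])
}

#' Heuristic pre-screening score for a pulse-wave window
#'
#' Six physiology- and statistics-consistency indicators, each in \[0, 1\]:
#' autocorrelation periodicity strength (maximum normalized autocorrelation at
#' lags 0.33--1.5 s), heart-band energy ratio (0.8--3 Hz over 0--50 Hz),
#' spike suppression (one minus the fraction of first-difference samples with
#' robust z-score above 6), baseline-drift suppression (one minus the energy
#' fraction below 0.4 Hz), inter-peak interval regularity (one minus the
#' capped coefficient of variation), and high-frequency noise suppression
#' (one minus the energy fraction above 10 Hz). The fused score `s_p` is
#' their unweighted mean. A constant window scores 0 on every indicator.
#'
#' @param x numeric window (will be standardized internally).
#' @param fs sampling rate, Hz.
#' @return list of the six indicators plus `s_p`.
#' @export
prescreen_score <- function(x, fs = 100) {
  zero <- list(periodicity_strength = 0, hr_band_ratio = 0, spike_score = 0,
               drift_score = 0, interval_regularity = 0, hf_noise_ratio = 0,
               s_p = 0)
  if (stats::sd(x) < 1e-12) return(zero)
  z <- standardize_window(x)
  n <- length(z)

  lag_lo <- max(1L, round(0.33 * fs))
  lag_hi <- min(n - 1L, round(1.5 * fs))
  ac <- stats::acf(z, lag.max = lag_hi, plot = FALSE, demean = TRUE)$acf[, 1, 1]
  periodicity <- max(0, min(1, max(ac[(lag_lo + 1L):(lag_hi + 1L)])))

  sp <- spectral_energy(z, fs)
  tot <- sum(sp$power[sp$freq > 0 & sp$freq <= 50])
  hr_band <- if (tot > 0) sum(sp$power[sp$freq >= 0.8 & sp$freq <= 3]) / tot else 0

  d <- diff(z)
  md <- stats::mad(d)
  rz <- if (md > 1e-12) abs(d - stats::median(d)) / md else abs(d - stats::median(d)) * Inf
  spike <- 1 - mean(rz > 6)

  drift <- if (tot > 0) 1 - sum(sp$power[sp$freq > 0 & sp$freq < 0.4]) / tot else 0

  pk <- find_pulse_peaks(z, fs)
  regularity <- if (length(pk) >= 3) {
    iv <- diff(pk)
    1 - min(1, stats::sd(iv) / mean(iv))
  } else 0

  hf <- if (tot > 0) 1 - sum(sp$power[sp$freq > 10]) / tot else 0

  out <- list(periodicity_strength = periodicity, hr_band_ratio = hr_band,
              spike_score = spike, drift_score = drift,
              interval_regularity = regularity, hf_noise_ratio = hf)
  out$s_p <- mean(unlist(out))
  out
}

#' Component weights of the quality index
#'
#' Reconstruction consistency 0.35, latent-space consistency 0.15,
#' morphological plausibility 0.30, physiological prior 0.20.
#'
#' @param w_R,w_L,w_M,w_P non-negative weights summing to 1.
#' @export
sqi_weights <- function(w_R = 0.35, w_L = 0.15, w_M = 0.3, w_P = 0.2) {
  w <- c(w_R = w_R, w_L = w_L, w_M = w_M, w_P = w_P)
  stopifnot(all(w >= 0), abs(sum(w) - 1) < 1e-9)
  w
}

#' Fuse component scores into the quality index
#'
#' `S = w_R S_R + w_L S_L + w_M S_M + w_P S_P`, an exact weighted sum.
#'
#' @param components numeric vector or 4-column matrix `(S_R, S_L, S_M, S_P)`.
#' @param weights a [sqi_weights()] vector.
#' @export
fuse_sqi <- function(components, weights = sqi_weights()) {
  if (is.matrix(components)) {
    stopifnot(ncol(components) == 4, all(components >= 0), all(components <= 1))
    as.numeric(components %*% weights)
  } else {
    stopifnot(length(components) == 4, all(components >= 0), all(components <= 1))
    sum(components * weights)
  }
}

#' Adaptive retention threshold
#'
#' Returns the score value `tau` such that the top `retain_fraction` of
#' segments (at least `ceiling(retain_fraction * N)`, more in case of ties)
#' satisfy `score >= tau`.
#'
#' @param scores numeric scores.
#' @param retain_fraction fraction to retain, in (0, 1\].
#' @export
adaptive_threshold <- function(scores, retain_fraction = 0.8) {
  stopifnot(length(scores) > 0, retain_fraction > 0, retain_fraction <= 1)
  n <- length(scores)
  k <- ceiling(retain_fraction * n)
  sort(scores)[n - k + 1L]
}

#' Screen dataset splits with a frozen quality scorer
#'
#' Scores every window of every split with the trained VAE quality index
#' (forward pass only), retains the top `retain_fraction` per split, and
#' attaches sample weights: the quality score rescaled so the retained
#' training segments have mean weight 1. The scorer must have been fitted on
#' training-split subjects only; a leakage guard raises otherwise.
#'
#' @param splits list with `train`, `val`, `test` datasets
#'   (see [split_by_subject()]).
#' @param vae calibrated VAE quality model from [fit_vae()].
#' @param weights component weights, see [sqi_weights()].
#' @param retain_fraction retention per split.
#' @return list with filtered `train`, `val`, `test` (each with a `$weight`
#'   field) and `sqi` (per-split scores, pass flags and thresholds).
#' @export
screen_dataset <- function(splits, vae, weights = sqi_weights(),
                           retain_fraction = 0.8) {
  stopifnot(all(c("train", "val", "test") %in% names(splits)))
  train_subjects <- unique(splits$train$subject)
  prov <- vae$trained_on
  if (is.null(prov)) stop("scorer provenance missing: fit_vae() records the training subjects")
  if (!all(prov %in% train_subjects)) {
    stop("leakage guard: quality scorer was fitted on subjects outside the training split")
  }
  score_split <- function(ds) {
    Z <- t(apply(ds$rpw, 1, standardize_window))
    comp <- component_scores(Z, vae, fs = ds$fs)
    s <- fuse_sqi(comp$components, weights)
    list(scores = s, components = comp$components)
  }
  sc <- lapply(splits[c("train", "val", "test")], score_split)
  out <- list()
  info <- list()
  for (nm in c("train", "val", "test")) {
    s <- sc[[nm]]$scores
    tau <- adaptive_threshold(s, retain_fraction)
    pass <- s >= tau
    ds <- dataset_subset(splits[[nm]], pass)
    ds$score <- s[pass]
    out[[nm]] <- ds
    info[[nm]] <- list(scores = s, tau = tau, pass = pass,
                       components = sc[[nm]]$components)
  }
  scale <- 1 / mean(out$train$score)
  for (nm in c("train", "val", "test")) out[[nm]]$weight <- out[[nm]]$score * scale
  out$sqi <- info
  out
}

#' Quality-score discrimination metrics against binary labels
#'
#' @param scores quality scores (higher = better quality).
#' @param labels logical or 0/1; `TRUE`/1 marks clean (high-quality) windows.
#' @param errors optional per-window estimation errors for the correlation
#'   metrics.
#' @return list with `roc_auc`, `average_precision`, `f1`,
#'   `pearson_r_vs_error`, `spearman_rho_vs_error`.
#' @export
evaluate_sqi <- function(scores, labels, errors = NULL) {
  stopifnot(all(is.finite(scores)), length(scores) == length(labels))
  y <- as.logical(labels)
  if (length(unique(y)) < 2) stop("labels must contain both classes")
  auc <- as.numeric(pROC::auc(pROC::roc(response = y, predictor = scores,
                                        quiet = TRUE, direction = "<",
                                        levels = c(FALSE, TRUE))))
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]
  prec <- cumsum(ys) / seq_along(ys)
  rec <- cumsum(ys) / sum(ys)
  ap <- sum(prec[ys]) / sum(ys)
  # F1 at the threshold maximizing F1 (predict clean when score >= threshold)
  tp <- cumsum(ys)
  fp <- seq_along(ys) - tp
  fn <- sum(ys) - tp
  f1 <- max(2 * tp / (2 * tp + fp + fn))
  pe <- se <- NA_real_
  if (!is.null(errors)) {
    pe <- stats::cor(scores, errors)
    se <- stats::cor(scores, errors, method = "spearman")
  }
  list(roc_auc = auc, average_precision = ap, f1 = f1,
       pearson_r_vs_error = pe, spearman_rho_vs_error = se)
}
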
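# Label-preserving augmentation for radar pulse-wave windows.

#' Augmentation configuration
#'
#' Five operators, each applied independently with probability
#' `op_probability`: circular time shift (up to `shift_frac` of the window),
#' amplitude scaling (uniform gain in `scale_range`), additive Gaussian noise
#' (`noise_sd` relative to the window's standard deviation), time warping
#' (uniform stretch/compress ratio in `warp_range`, interpolated back to the
#' original length), and sinusoidal baseline wander (`wander_amp` at
#' `wander_freq`). `factor` augmented copies are generated per original.
#'
#' @param factor copies per original window.
#' @param op_probability per-operator application probability.
#' @param shift_frac maximum circular shift as a fraction of the window.
#' @param scale_range amplitude gain range.
#' @param noise_sd Gaussian noise level relative to the window sd.
#' @param warp_range time-warp ratio range.
#' @param wander_amp baseline-wander amplitude (standardized scale).
#' @param wander_freq baseline-wander frequency, Hz.
#' @export
augment_config <- function(factor = 3L, op_probability = 0.5, shift_frac = 0.10,
                           scale_range = c(0.9, 1.1), noise_sd = 0.02,
                           warp_range = c(0.95, 1.05), wander_amp = 0.05,
                           wander_freq = 0.5) {
  stopifnot(factor >= 0, op_probability >= 0, op_probability <= 1,
            shift_frac >= 0, scale_range[1] <= scale_range[2],
            warp_range[1] <= warp_range[2], noise_sd >= 0)
  structure(list(factor = as.integer(factor), op_probability = op_probability,
                 shift_frac = shift_frac, scale_range = scale_range,
                 noise_sd = noise_sd, warp_range = warp_range,
                 wander_amp = wander_amp, wander_freq = wander_freq),
            class = "augment_config")
}

circular_shift <- function(x, s) {
  L <- length(x)
  s <- ((s %% L) + L) %% L
  if (s == 0) return(x)
  c(x[(L - s + 1L):L], x[1L:(L - s)])
}

time_warp <- function(x, ratio) {
  L <- length(x)
  n_res <- max(2L, round(L * ratio))
  warped <- stats::approx(seq_len(L), x, xout = seq(1, L, length.out = n_res))$y
  stats::approx(seq_len(n_res), warped, xout = seq(1, n_res, length.out = L))$y
}

#' Apply the augmentation operators to one window
#'
#' Operators are applied in a fixed order (shift, scale, warp, noise,
#' wander), each with probability `config$op_probability`; draws come from
#' the current RNG state (or `rng_seed` when given). Labels are untouched by
#' construction; output length always equals input length.
#'
#' @param segment numeric window (standardized scale).
#' @param config an [augment_config()].
#' @param rng_seed optional seed.
#' @param fs sampling rate for the baseline wander, Hz.
#' @param force_ops optional logical vector of length 5 overriding the random
#'   on/off draws (order: shift, scale, warp, noise, wander) — useful for
#'   testing individual operators.
#' @return augmented numeric window of the same length.
#' @export
apply_augmentation <- function(segment, config = augment_config(), rng_seed = NULL,
                               fs = 100, force_ops = NULL) {
  run <- function() {
    L <- length(segment)
    on <- if (is.null(force_ops)) stats::runif(5) < config$op_probability
          else rep_len(force_ops, 5L)
    x <- segment
    if (on[1]) {
      smax <- round(config$shift_frac * L)
      if (smax > 0) x <- circular_shift(x, sample(-smax:smax, 1L))
    }
    if (on[2]) x <- x * stats::runif(1, config$scale_range[1], config$scale_range[2])
    if (on[3]) x <- time_warp(x, stats::runif(1, config$warp_range[1], config$warp_range[2]))
    if (on[4]) x <- x + stats::rnorm(L, sd = config$noise_sd * stats::sd(segment))
    if (on[5]) {
      t <- (seq_len(L) - 1) / fs
      x <- x + config$wander_amp * sin(2 * pi * config$wander_freq * t +
                                         stats::runif(1, 0, 2 * pi))
    }
    x
  }
  if (is.null(rng_seed)) run() else local_seed(rng_seed, run())
}

#' Augment a training dataset
#'
#' Appends `config$factor` augmented copies of every window; copies inherit
#' the subject id and the blood-pressure / waveform labels unchanged, so the
#' result holds `(factor + 1)` times the original window count. Augmentation
#' is restricted to the training split: applying it to a dataset marked as a
#' validation or test split raises an error.
#'
#' @param ds an `rpw_dataset` (training split).
#' @param config an [augment_config()].
#' @param rng_seed seed controlling all draws.
#' @return augmented `rpw_dataset` with an `$augmented` flag per window.
#' @export
augment_dataset <- function(ds, config = augment_config(), rng_seed = 1L) {
  stopifnot(inherits(ds, "rpw_dataset"))
  split <- attr(ds, "split")
  if (!is.null(split) && split != "train") {
    stop("augmentation leakage guard: refusing to augment the '", split, "' split")
  }
  N <- dataset_size(ds)
  f <- config$factor
  local_seed(rng_seed, {
    reps <- lapply(seq_len(N), function(i) {
      t(vapply(seq_len(f),
               function(.) apply_augmentation(ds$rpw[i, ], config, fs = ds$fs),
               numeric(ncol(ds$rpw))))
    })
    out <- ds
    out$rpw <- rbind(ds$rpw, do.call(rbind, reps))
    idx <- rep(seq_len(N), each = f)
    out$abp <- rbind(ds$abp, ds$abp[idx, , drop = FALSE])
    for (fld in c("sbp", "dbp", "heart_rate", "subject", "corrupt",
                  "corrupt_kind", "weight", "score")) {
      if (!is.null(ds[[fld]])) out[[fld]] <- c(ds[[fld]], ds[[fld]][idx])
    }
    out$augmented <- c(rep(FALSE, N), rep(TRUE, N * f))
    out
  })
}
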
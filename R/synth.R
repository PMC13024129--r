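# Synthetic radar / hemodynamics generators.
#
# Every generator is a pure function of its parameters and seed: the caller's
# RNG state is saved and restored around any internal draws.

local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' FMCW radar configuration
#'
#' Defaults follow a 77 GHz automotive-band vital-sign setup: 3 GHz sweep
#' bandwidth over a 60 microsecond chirp (50 MHz/us slope), 64 fast-time
#' samples at 2 MHz, four receive channels at half-wavelength spacing.
#'
#' @param f_c carrier (chirp start) frequency, Hz.
#' @param B sweep bandwidth, Hz.
#' @param T_c chirp duration, s.
#' @param n_chirps number of chirps (slow-time length).
#' @param n_fast fast-time samples per chirp.
#' @param fast_rate fast-time ADC rate, Hz.
#' @param slow_rate chirp repetition rate used for motion sampling, Hz.
#' @param n_rx receive channels.
#' @param phi0 initial phase, rad.
#' @param A_T transmit amplitude.
#' @return a `radar_config` list; `$frequency_slope` and `$wavelength` are
#'   derived fields.
#' @export
radar_config <- function(f_c = 77e9, B = 3e9, T_c = 60e-6, n_chirps = 2048L,
                         n_fast = 64L, fast_rate = 2e6, slow_rate = 200,
                         n_rx = 4L, phi0 = 0, A_T = 1) {
  stopifnot(f_c > 0, B > 0, T_c > 0, n_chirps >= 1, n_fast >= 1, n_rx >= 1)
  cfg <- list(f_c = f_c, B = B, T_c = T_c, frequency_slope = B / T_c,
              n_chirps = as.integer(n_chirps), n_fast = as.integer(n_fast),
              fast_rate = fast_rate, slow_rate = slow_rate,
              n_rx = as.integer(n_rx), phi0 = phi0, A_T = A_T,
              wavelength = 299792458 / f_c)
  stopifnot(abs(cfg$frequency_slope - B / T_c) <= 1e-6 * cfg$frequency_slope)
  class(cfg) <- "radar_config"
  cfg
}

#' Chest micro-motion model
#'
#' Superposes a cardiac micro-displacement (hundreds of micrometres) on a
#' respiratory drift, sampled at the chirp repetition rate.
#'
#' @param R0 static chest range, m.
#' @param n_samples number of slow-time samples.
#' @param fs slow-time sampling rate, Hz.
#' @param heart_rate,resp_rate cardiac / respiratory frequencies, Hz.
#' @param cardiac_amp,resp_amp displacement amplitudes, m.
#' @param cardiac_wave optional custom cardiac displacement (length
#'   `n_samples`, m); overrides the sinusoidal default.
#' @return a `chest_motion` list with `$displacement`, `$cardiac`,
#'   `$respiratory` (all length `n_samples`).
#' @export
chest_motion <- function(R0 = 0.6, n_samples = 2048L, fs = 200,
                         heart_rate = 1.2, resp_rate = 0.25,
                         cardiac_amp = 2e-4, resp_amp = 8e-4,
                         cardiac_wave = NULL) {
  t <- (seq_len(n_samples) - 1) / fs
  cardiac <- if (is.null(cardiac_wave)) cardiac_amp * sin(2 * pi * heart_rate * t)
             else cardiac_wave
  stopifnot(length(cardiac) == n_samples)
  resp <- resp_amp * sin(2 * pi * resp_rate * t)
  x <- cardiac + resp
  stopifnot(all(abs(x) < R0))
  structure(list(R0 = R0, displacement = x, cardiac = cardiac, respiratory = resp,
                 heart_rate = heart_rate, resp_rate = resp_rate, fs = fs),
            class = "chest_motion")
}

#' Hemodynamic parameters for the synthetic arterial waveform
#'
#' @param sbp,dbp systolic / diastolic pressure, mmHg (`sbp > dbp > 0`).
#' @param heart_rate cardiac frequency, Hz (0.66--3).
#' @param notch_depth dicrotic bump amplitude as a fraction of pulse height.
#' @param upstroke_fraction phase position of the systolic peak within the
#'   cycle, in (0, 1).
#' @param coupling_gain radians of radar phase per unit normalized pulse.
#' @param noise_sd additive noise level (mmHg on pressure waveforms,
#'   standardized units on radar pulse waves).
#' @export
hemo_params <- function(sbp = 120, dbp = 80, heart_rate = 1.2, notch_depth = 0.25,
                        upstroke_fraction = 0.16, coupling_gain = 1,
                        noise_sd = 0) {
  if (!(sbp > dbp) || dbp <= 0) stop("non-physiological parameters: require sbp > dbp > 0")
  if (upstroke_fraction <= 0 || upstroke_fraction >= 1) stop("upstroke_fraction must be in (0, 1)")
  if (heart_rate < 0.66 || heart_rate > 3) stop("heart_rate must be within [0.66, 3] Hz")
  structure(list(sbp = sbp, dbp = dbp, heart_rate = heart_rate,
                 notch_depth = notch_depth, upstroke_fraction = upstroke_fraction,
                 coupling_gain = coupling_gain, noise_sd = noise_sd),
            class = "hemo_params")
}

# per-cycle pulse template on phase u in [0, 1): systolic Gaussian bump,
# dicrotic bump a quarter cycle later, exponential diastolic decay
abp_cycle_shape <- function(u, notch_depth, upstroke_fraction) {
  c1 <- upstroke_fraction
  s1 <- 0.085
  c2 <- c1 + 0.24
  s2 <- 0.10
  exp(-0.5 * ((u - c1) / s1)^2) +
    notch_depth * exp(-0.5 * ((u - c2) / s2)^2) +
    0.55 * exp(-u / 0.45)
}

#' Generate a synthetic arterial blood-pressure waveform
#'
#' Each cardiac cycle is a two-bump (systolic + dicrotic) template with an
#' exponential diastolic decay, affinely anchored per cycle so that the cycle
#' maximum equals `sbp` and the minimum equals `dbp` before noise.
#'
#' @param params a [hemo_params()] object.
#' @param length number of samples (at least one full cycle).
#' @param fs sampling rate, Hz.
#' @param rng_seed seed for the additive noise.
#' @return numeric vector (mmHg).
#' @export
generate_abp_waveform <- function(params, length = 1000L, fs = 100, rng_seed = 1L) {
  stopifnot(inherits(params, "hemo_params"))
  if (length < fs / params$heart_rate) stop("length must cover at least one full cardiac cycle")
  t <- (seq_len(length) - 1) / fs
  ph <- t * params$heart_rate
  u <- ph %% 1
  raw <- abp_cycle_shape(u, params$notch_depth, params$upstroke_fraction)
  # anchor against the full-cycle template range (dense phase grid)
  ug <- seq(0, 1, length.out = 2049L)[-2049L]
  rg <- abp_cycle_shape(ug, params$notch_depth, params$upstroke_fraction)
  lo <- min(rg); hi <- max(rg)
  abp <- params$dbp + (raw - lo) / (hi - lo) * (params$sbp - params$dbp)
  if (params$noise_sd > 0) {
    abp <- abp + local_seed(rng_seed, stats::rnorm(length, sd = params$noise_sd))
  }
  abp
}

#' Derive a radar pulse wave from an arterial waveform
#'
#' The chest micro-displacement pulse is modelled as a smoothed,
#' amplitude-normalized transform of the arterial waveform plus measurement
#' noise; morphology (peak and notch timing) is preserved.
#'
#' @param abp numeric arterial waveform.
#' @param params [hemo_params()]; `noise_sd` sets the additive noise level on
#'   the normalized scale and `coupling_gain` the overall amplitude.
#' @param rng_seed noise seed.
#' @param smooth_k moving-average width in samples (1 = identity smoothing).
#' @return numeric vector (dimensionless radar pulse wave).
#' @export
derive_rpw_from_abp <- function(abp, params, rng_seed = 1L, smooth_k = 5L) {
  if (!all(is.finite(abp))) stop("abp must be finite")
  x <- if (smooth_k > 1L) {
    as.numeric(stats::filter(abp, rep(1 / smooth_k, smooth_k), sides = 2))
  } else abp
  # shrink the average at the edges instead of dropping samples
  if (smooth_k > 1L) {
    h <- (smooth_k - 1L) %/% 2L
    n <- length(abp)
    for (i in which(is.na(x))) {
      lo <- max(1L, i - h); hi <- min(n, i + h)
      x[i] <- mean(abp[lo:hi])
    }
  }
  s <- stats::sd(x)
  x <- params$coupling_gain * (x - mean(x)) / (s + 1e-12)
  if (params$noise_sd > 0) {
    x <- x + local_seed(rng_seed, stats::rnorm(length(x), sd = params$noise_sd))
  }
  x
}

#' Simulate a multi-channel FMCW radar cube
#'
#' Produces the intermediate-frequency signal of a point chest target at
#' `motion$R0 + x(t)`: per chirp the target contributes a beat tone whose
#' frequency is proportional to range and whose phase varies as
#' `4 pi x(t) / lambda`; a stationary clutter reflector, per-channel complex
#' DC offsets and receiver noise can be added. Receive channels carry the
#' far-field phase of a uniform linear array with half-wavelength spacing
#' (phase delay increasing with channel index for positive angles).
#'
#' @param motion a [chest_motion()] object sampled at the chirp rate.
#' @param cfg a [radar_config()].
#' @param clutter_amp amplitude of the static reflector (0 disables).
#' @param dc_offset complex scalar or length-`n_rx` vector of DC offsets.
#' @param rng_seed seed for receiver noise.
#' @param target_angle chest direction, rad.
#' @param clutter_range,clutter_angle static reflector geometry.
#' @param noise_sd complex receiver noise standard deviation.
#' @return a `radar_cube`: complex array `(n_chirps, n_fast, n_rx)` with the
#'   configuration attached.
#' @export
simulate_radar_cube <- function(motion, cfg, clutter_amp = 0, dc_offset = 0,
                                rng_seed = 1L, target_angle = 0,
                                clutter_range = 1.5, clutter_angle = 0.3,
                                noise_sd = 0) {
  stopifnot(inherits(motion, "chest_motion"), inherits(cfg, "radar_config"))
  M <- cfg$n_chirps
  if (length(motion$displacement) < M) stop("motion must provide at least n_chirps samples")
  c0 <- 299792458
  lam <- cfg$wavelength
  d <- lam / 2
  tn <- (seq_len(cfg$n_fast) - 1) / cfg$fast_rate
  Rm <- motion$R0 + motion$displacement[seq_len(M)]
  dc <- rep_len(dc_offset, cfg$n_rx)
  cube <- array(0i, c(M, cfg$n_fast, cfg$n_rx))
  tone <- function(R, angle, amp, ch) {
    fb <- 2 * cfg$frequency_slope * R / c0
    geo <- -2 * pi * d * (ch - 1) * sin(angle) / lam
    amp * exp(1i * (2 * pi * outer(fb, tn) + 4 * pi * R / lam + geo + cfg$phi0))
  }
  for (ch in seq_len(cfg$n_rx)) {
    s <- tone(Rm, target_angle, cfg$A_T, ch)
    if (clutter_amp != 0) {
      s <- s + tone(rep(clutter_range, M), clutter_angle, clutter_amp, ch)
    }
    s <- s + dc[ch]
    cube[, , ch] <- s
  }
  if (noise_sd > 0) {
    cube <- cube + local_seed(rng_seed, {
      array(complex(real = stats::rnorm(length(cube), sd = noise_sd / sqrt(2)),
                    imaginary = stats::rnorm(length(cube), sd = noise_sd / sqrt(2))),
            dim(cube))
    })
  }
  structure(cube, cfg = cfg, target_angle = target_angle, class = "radar_cube")
}

#' Corruption specification
#' @param kind one of `"spike"`, `"drift"`, `"noise_burst"`, `"dropout"`,
#'   `"aperiodic"`.
#' @param severity in \[0, 1\]; 0 leaves the segment untouched.
#' @export
corruption_spec <- function(kind, severity = 1) {
  kinds <- c("spike", "drift", "noise_burst", "dropout", "aperiodic")
  if (!kind %in% kinds) stop("unknown corruption kind: ", kind)
  stopifnot(severity >= 0, severity <= 1)
  structure(list(kind = kind, severity = severity), class = "corruption_spec")
}

#' Inject a labelled corruption into a pulse-wave segment
#'
#' @param segment numeric vector.
#' @param spec a [corruption_spec()].
#' @param rng_seed seed controlling positions and amplitudes.
#' @return list with `$x` (modified segment) and `$label` (`"clean"` or
#'   `"corrupted"`).
#' @export
inject_corruption <- function(segment, spec, rng_seed = 1L) {
  stopifnot(all(is.finite(segment)), inherits(spec, "corruption_spec"))
  if (spec$severity == 0) return(list(x = segment, label = "clean"))
  L <- length(segment)
  s <- stats::sd(segment)
  if (s == 0) s <- 1
  sev <- spec$severity
  x <- local_seed(rng_seed, switch(spec$kind,
    spike = {
      n_sp <- 1L + round(sev * 4)
      pos <- sample.int(L, n_sp)
      out <- segment
      out[pos] <- out[pos] + sample(c(-1, 1), n_sp, replace = TRUE) * (5 + 10 * sev) * s
      out
    },
    drift = {
      t <- (seq_len(L) - 1) / L
      segment + sev * s * (3 * sin(2 * pi * 1.5 * t + stats::runif(1, 0, 2 * pi)) +
                             2 * (t - 0.5))
    },
    noise_burst = {
      span <- max(5L, round(L * (0.1 + 0.2 * sev)))
      st <- sample.int(L - span + 1L, 1L)
      out <- segment
      idx <- st:(st + span - 1L)
      out[idx] <- out[idx] + stats::rnorm(span, sd = 4 * sev * s)
      out
    },
    dropout = {
      span <- max(5L, round(L * 0.3 * sev))
      st <- sample.int(L - span + 1L, 1L)
      out <- segment
      out[st:(st + span - 1L)] <- 0
      out
    },
    aperiodic = {
      # Fourier phase scrambling destroys periodic structure but keeps the
      # power spectrum; blend with the original according to severity
      X <- stats::fft(segment)
      n2 <- L %/% 2
      phase <- stats::runif(n2 - 1, 0, 2 * pi)
      Xs <- X
      Xs[2:n2] <- Mod(X[2:n2]) * exp(1i * phase)
      Xs[(L - n2 + 2):L] <- Conj(rev(Xs[2:n2]))
      scr <- Re(stats::fft(Xs, inverse = TRUE)) / L
      (1 - sev) * segment + sev * scr
    }))
  list(x = x, label = "corrupted")
}

#' Build a synthetic radar-pulse-wave dataset with paired blood pressure
#'
#' Per subject, systolic pressure is drawn uniformly on \[95, 165\] mmHg and
#' diastolic on \[55, 100\] mmHg (re-drawn until the pulse pressure is at
#' least 25 mmHg), heart rate uniformly on \[0.8, 1.8\] Hz. Pulse morphology
#' is coupled to pressure (systolic width narrows with higher SBP; dicrotic
#' bump deepens with higher DBP) so that the waveform is informative about
#' the labels. Within a subject's session, both pressures are modulated by a
#' slow sinusoid of amplitude 10 mmHg. Exactly
#' `round(corrupt_fraction * total)` windows are corrupted with a random kind
#' and a severity drawn from `severity_range`.
#'
#' @param n_subjects at least 3 (subject-wise splitting needs 3 groups).
#' @param windows_per_subject windows per subject.
#' @param corrupt_fraction fraction of windows to corrupt.
#' @param rng_seed master seed.
#' @param L window length in samples.
#' @param fs sampling rate, Hz.
#' @param severity_range corruption severity range (uniform draw).
#' @param rpw_noise_sd additive noise on the clean pulse waves.
#' @return an `rpw_dataset` list: matrices `rpw`, `abp` (`N x L`), vectors
#'   `sbp`, `dbp`, `heart_rate`, `subject`, `corrupt`, `corrupt_kind`, plus
#'   `fs`, `L`, `schema_version`.
#' @export
make_dataset <- function(n_subjects, windows_per_subject, corrupt_fraction = 0,
                         rng_seed = 1L, L = 1000L, fs = 100,
                         severity_range = c(0.5, 1), rpw_noise_sd = 0.05) {
  if (n_subjects < 3) stop("n_subjects must be at least 3")
  stopifnot(corrupt_fraction >= 0, corrupt_fraction <= 1)
  local_seed(rng_seed, {
    N <- n_subjects * windows_per_subject
    rpw <- matrix(0, N, L)
    abp <- matrix(0, N, L)
    sbp <- dbp <- hr <- numeric(N)
    subject <- integer(N)
    i <- 0L
    for (s in seq_len(n_subjects)) {
      sbp0 <- stats::runif(1, 95, 165)
      repeat {
        dbp0 <- stats::runif(1, 55, 100)
        if (sbp0 - dbp0 >= 25) break
      }
      hr0 <- stats::runif(1, 0.8, 1.8)
      phase0 <- stats::runif(1, 0, 2 * pi)
      for (w in seq_len(windows_per_subject)) {
        i <- i + 1L
        mod <- sin(phase0 + 2 * pi * (w - 1) / max(1, windows_per_subject))
        sbp_w <- sbp0 + 10 * mod
        dbp_w <- dbp0 + 10 * mod
        hr_w <- min(1.8, max(0.8, hr0 + stats::rnorm(1, sd = 0.03)))
        pars <- hemo_params(
          sbp = sbp_w, dbp = dbp_w, heart_rate = hr_w,
          notch_depth = 0.15 + 0.4 * (dbp_w - 45) / 65,
          upstroke_fraction = 0.10 + 0.20 * (175 - sbp_w) / 90,
          noise_sd = rpw_noise_sd)
        seed_w <- sample.int(2^30, 1L)
        a <- generate_abp_waveform(
          hemo_params(pars$sbp, pars$dbp, pars$heart_rate, pars$notch_depth,
                      pars$upstroke_fraction, noise_sd = 0),
          length = L, fs = fs, rng_seed = seed_w)
        r <- derive_rpw_from_abp(a, pars, rng_seed = seed_w)
        rpw[i, ] <- r
        abp[i, ] <- a
        sbp[i] <- sbp_w
        dbp[i] <- dbp_w
        hr[i] <- hr_w
        subject[i] <- s
      }
    }
    n_cor <- round(corrupt_fraction * N)
    corrupt <- rep(FALSE, N)
    kind <- rep(NA_character_, N)
    if (n_cor > 0) {
      kinds <- c("spike", "drift", "noise_burst", "dropout", "aperiodic")
      idx <- sample.int(N, n_cor)
      for (j in idx) {
        k <- sample(kinds, 1L)
        sev <- stats::runif(1, severity_range[1], severity_range[2])
        out <- inject_corruption(rpw[j, ], corruption_spec(k, sev),
                                 rng_seed = sample.int(2^30, 1L))
        rpw[j, ] <- out$x
        corrupt[j] <- TRUE
        kind[j] <- k
      }
    }
    structure(list(rpw = rpw, abp = abp, sbp = sbp, dbp = dbp, heart_rate = hr,
                   subject = subject, corrupt = corrupt, corrupt_kind = kind,
                   fs = fs, L = L, schema_version = "1.0"),
              class = "rpw_dataset")
  })
}

#' Build a parameter-recovery dataset with a known pulse-timing to pressure map
#'
#' Windows are clean synthetic pulse waves whose heart rate varies across
#' windows; the blood-pressure labels are a known smooth (affine) function of
#' the heart rate plus independent Gaussian label noise:
#' `SBP = 72 + 40 hr + noise`, `DBP = 45 + 25 hr + noise` (mmHg, `hr` in Hz).
#' Since the waveform determines `hr` exactly, the label noise standard
#' deviation is the irreducible error floor of any predictor, which makes the
#' dataset suitable for end-to-end recovery checks at small scale. Heart rate
#' varies mostly within subjects (emulating sessions with provocations that
#' perturb hemodynamics), so any subject-wise split spans the full label
#' range.
#'
#' @param n_subjects number of subjects (heart-rate base drawn per subject).
#' @param windows_per_subject windows per subject.
#' @param rng_seed master seed.
#' @param L window length (default 256 samples for the tiny model profile).
#' @param fs sampling rate, Hz.
#' @param label_noise_sd Gaussian label noise, mmHg.
#' @param rpw_noise_sd additive waveform noise (standardized scale).
#' @param corrupt_fraction fraction of windows corrupted (with ground-truth
#'   labels), as in [make_dataset()].
#' @param severity_range corruption severity range.
#' @return an `rpw_dataset`; the noiseless labels are kept in `sbp_true`,
#'   `dbp_true`.
#' @export
make_mapping_dataset <- function(n_subjects, windows_per_subject, rng_seed = 1L,
                                 L = 256L, fs = 100, label_noise_sd = 1.5,
                                 rpw_noise_sd = 0.02, corrupt_fraction = 0,
                                 severity_range = c(0.5, 1)) {
  if (n_subjects < 3) stop("n_subjects must be at least 3")
  local_seed(rng_seed, {
    N <- n_subjects * windows_per_subject
    rpw <- matrix(0, N, L)
    abp <- matrix(0, N, L)
    sbp <- dbp <- sbp_true <- dbp_true <- hr <- numeric(N)
    subject <- integer(N)
    i <- 0L
    for (s in seq_len(n_subjects)) {
      hr0 <- stats::runif(1, 1.1, 1.5)
      for (w in seq_len(windows_per_subject)) {
        i <- i + 1L
        hr_w <- min(1.8, max(0.8, hr0 + stats::rnorm(1, sd = 0.18)))
        st <- 72 + 40 * hr_w
        dt <- 45 + 25 * hr_w
        pars <- hemo_params(sbp = st, dbp = dt, heart_rate = hr_w,
                            noise_sd = rpw_noise_sd)
        seed_w <- sample.int(2^30, 1L)
        a <- generate_abp_waveform(
          hemo_params(st, dt, hr_w, pars$notch_depth, pars$upstroke_fraction),
          length = L, fs = fs, rng_seed = seed_w)
        rpw[i, ] <- derive_rpw_from_abp(a, pars, rng_seed = seed_w)
        abp[i, ] <- a
        sbp_true[i] <- st
        dbp_true[i] <- dt
        sbp[i] <- st + stats::rnorm(1, sd = label_noise_sd)
        dbp[i] <- dt + stats::rnorm(1, sd = label_noise_sd)
        hr[i] <- hr_w
        subject[i] <- s
      }
    }
    corrupt <- rep(FALSE, N)
    kind <- rep(NA_character_, N)
    n_cor <- round(corrupt_fraction * N)
    if (n_cor > 0) {
      kinds <- c("spike", "drift", "noise_burst", "dropout", "aperiodic")
      for (j in sample.int(N, n_cor)) {
        k <- sample(kinds, 1L)
        sev <- stats::runif(1, severity_range[1], severity_range[2])
        rpw[j, ] <- inject_corruption(rpw[j, ], corruption_spec(k, sev),
                                      rng_seed = sample.int(2^30, 1L))$x
        corrupt[j] <- TRUE
        kind[j] <- k
      }
    }
    structure(list(rpw = rpw, abp = abp, sbp = sbp, dbp = dbp,
                   sbp_true = sbp_true, dbp_true = dbp_true, heart_rate = hr,
                   subject = subject, corrupt = corrupt,
                   corrupt_kind = kind,
                   fs = fs, L = as.integer(L), label_noise_sd = label_noise_sd,
                   schema_version = "1.0"),
              class = "rpw_dataset")
  })
}

#' Number of windows in a dataset
#' @param ds an `rpw_dataset`.
#' @export
dataset_size <- function(ds) nrow(ds$rpw)

#' Subset a dataset by window index
#' @param ds an `rpw_dataset`.
#' @param idx integer or logical index over windows.
#' @export
dataset_subset <- function(ds, idx) {
  out <- ds
  out$rpw <- ds$rpw[idx, , drop = FALSE]
  out$abp <- ds$abp[idx, , drop = FALSE]
  for (f in c("sbp", "dbp", "sbp_true", "dbp_true", "heart_rate", "subject",
              "corrupt", "corrupt_kind", "weight", "score", "augmented")) {
    if (!is.null(ds[[f]])) out[[f]] <- ds[[f]][idx]
  }
  out
}

#' Serialize / load a dataset
#'
#' Datasets follow a fixed schema (window matrices plus per-window labels and
#' a `schema_version` field) and are stored with R's native serializer.
#'
#' @param ds an `rpw_dataset`.
#' @param path file path.
#' @export
write_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "rpw_dataset"))
  saveRDS(ds, path, version = 3)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  ds <- readRDS(path)
  stopifnot(inherits(ds, "rpw_dataset"))
  ds
}
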
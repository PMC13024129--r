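# radarbp

Contactless blood-pressure estimation from frequency-modulated
continuous-wave (FMCW) radar, end to end, in R.

A 77 GHz radar pointed at the chest resolves the sub-millimetre skin
displacement of each heartbeat. The displacement waveform — the radar pulse
wave (RPW) — encodes arterial morphology (systolic upstroke, dicrotic notch,
diastolic decay) that is tightly coupled to blood pressure. `radarbp`
implements the full estimation stack for this problem:

- **Signal processing**: slow-time clutter suppression, range compression,
  digital beamforming with automatic range–angle selection, sliding-window
  DC removal, extended differentiate-and-cross-multiply (DACM) phase
  demodulation `Phi[n] = sum_k (I dQ - Q dI) / (I^2 + Q^2)`, and zero-phase
  band-pass pulse extraction at 100 Hz.
- **Unsupervised quality screening (VAE-SQI)**: six heuristic physiology
  indicators fused into a pre-screening score, a 1-D variational
  autoencoder trained in two stages (top-35% pre-screened subset, then full
  data; KL weight warmed up 0.01 to 0.5 over 30 epochs), and a four-component
  quality index `S = 0.35 S_R + 0.15 S_L + 0.30 S_M + 0.20 S_P`
  (reconstruction consistency, latent distance to the high-quality centre,
  morphological plausibility, physiological prior) with top-80% retention
  and quality-derived sample weights.
- **Label-preserving augmentation**: circular time shift (±10%), amplitude
  scaling (0.9–1.1), Gaussian noise (sigma 0.02 of window SD), time warping
  (0.95–1.05), sinusoidal baseline wander (0.05 at 0.5 Hz); three copies per
  window, each operator applied with probability 0.5, training split only.
- **MARU-MTL network**: residual U-Net encoder (channels up to 1024), a
  multi-scale bottleneck (kernels 1/3/5) with channel–temporal attention, a
  bidirectional Mamba (selective state-space) block with a linear-time scan,
  attention-gated skips, and two heads: `(SBP, DBP)` regression and
  arterial-waveform reconstruction. Trained with
  `L = 2.0 Huber(SBP) + Huber(DBP) + 0.01 SmoothL1(IN(abp), IN(abp_ref))`
  (Huber threshold 1 mmHg), AdamW, cosine annealing, early stopping.
- **Evaluation harness**: subject-wise 70/10/20 splits, ME/SD/MAE/RMSE/
  Pearson r, cumulative 5/10/15 mmHg percentages, AAMI check
  (|ME| <= 5, SD <= 8 mmHg), BHS grading (A: 60/85/95), Bland–Altman, and
  ablation runners (auxiliary-loss sweep, retention sweep, bottleneck and
  temporal-module variants).
- **Simulator**: parametric chest motion + FMCW echo rendering (radar
  cubes), a hemodynamic generator producing paired (RPW, ABP, SBP, DBP)
  windows with controllable labelled corruption — every test input is
  generated in code; no external data is needed.

All neural components run on a package-internal reverse-mode automatic
differentiation engine (verified against finite differences), so no deep
learning framework is required; a `tiny` model profile trains on one CPU.

## Worked example

Simulate a radar cube of a breathing, beating chest behind clutter and DC
offsets, recover the pulse wave, and check where the energy came from:

```r
library(radarbp)

cfg  <- radar_config(n_chirps = 4096)          # 77 GHz, 3 GHz sweep, 4 RX
mot  <- chest_motion(R0 = 0.5625, n_samples = 4096, heart_rate = 1.2,
                     cardiac_amp = 2e-4, resp_amp = 8e-4)
cube <- simulate_radar_cube(mot, cfg, clutter_amp = 2,
                            dc_offset = complex(real = 0.5, imaginary = -0.3),
                            target_angle = 10 * pi / 180)
out <- preprocess_cube(cube)
out$range_bin                                   # 7   (= 0.5625 m at 50 MHz/us)
round(out$theta * 180 / pi, 1)                  # 10  (degrees)
ref <- extract_rpw(mot$cardiac - mean(mot$cardiac), fs = mot$fs)
round(cor(out$rpw[1:2040], ref[1:2040]), 3)     # 0.995
```

The recovered pulse wave correlates at 0.995 with the band-passed true
cardiac displacement; the target's range bin and steering angle are
identified exactly.

Screen a synthetic dataset with the quality index and grade a model-sized
error distribution:

```r
ds <- make_dataset(6, 12, corrupt_fraction = 0.3, rng_seed = 42, L = 400)
Z  <- t(apply(ds$rpw, 1, standardize_window))
vae <- fit_vae(Z, config = vae_config("tiny", input_len = 400), rng_seed = 42,
               epochs_stage1 = 4, epochs_stage2 = 2,
               subjects = unique(ds$subject))
S <- fuse_sqi(component_scores(Z, vae, fs = ds$fs)$components)
round(evaluate_sqi(S, !ds$corrupt)$roc_auc, 2)  # 0.95

aami_check(0.07, 5.90)                          # TRUE
bhs_grade(75.7, 92.1, 97.0)                     # "A"
```

Even this six-epoch toy fit separates corrupted from clean windows with
ROC-AUC 0.95; the acceptance suite runs the full reduced protocol (30 + 15
epochs on 20 subjects) and reaches 0.955. The grading calls show the AAMI pass and BHS grade A implied by a
0.07 mmHg mean error, 5.90 mmHg SD, and 75.7/92.1/97.0% cumulative errors.

The methods vignette (`vignettes/radarbp-methods.Rmd`) documents the models,
parameter choices and limitations in detail.

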
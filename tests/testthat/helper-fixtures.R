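# Small shared fixtures; everything is generated in code.

# clean standardized pulse train at a given heart rate
pulse_train <- function(hr = 1.2, L = 1000L, fs = 100) {
  p <- hemo_params(sbp = 120, dbp = 80, heart_rate = hr)
  a <- generate_abp_waveform(p, L, fs, rng_seed = 1)
  standardize_window(derive_rpw_from_abp(a, p))
}

# tiny fitted VAE on a small dataset; built once per test run
tiny_vae_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- make_dataset(6, 12, corrupt_fraction = 0.3, rng_seed = 42, L = 400)
      Z <- t(apply(ds$rpw, 1, standardize_window))
      sp <- apply(Z, 1, function(w) prescreen_score(w, ds$fs)$s_p)
      vae <- fit_vae(Z, sp, vae_config("tiny", input_len = 400), rng_seed = 42,
                     epochs_stage1 = 4, epochs_stage2 = 2,
                     subjects = unique(ds$subject))
      cache <<- list(ds = ds, Z = Z, sp = sp, vae = vae)
    }
    cache
  }
})
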